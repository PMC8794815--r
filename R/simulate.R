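#' Build a synthetic operon-structured replicon
#'
#' Generates a single bacterial-style replicon of operons with leadered genes.
#' Each CDS starts with ATG and ends with a stop codon; the base immediately
#' upstream of each start codon (the -1 base) is drawn from
#' \code{minus1BaseWeights} and written into the sequence. With probability
#' \code{overlapProbability}, a non-first operonic gene is placed so that its
#' start codon overlaps the upstream stop codon (the classic ATGA geometry:
#' the ATG begins one base before the TGA), the configuration in which
#' translational coupling by reinitiation is strongest.
#'
#' @param config a [SimConfig-class].
#' @return A [SimGenome-class]. Deterministic given \code{config@seed}.
#' @examples
#' gn <- buildGenome(simConfig(nOperons = 5L, seed = 7L))
#' geneModels(gn)
#' @export
buildGenome <- function(config) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  set.seed(config@seed)

  flank <- 200L
  operonGap <- c(100L, 300L)
  cisGap <- c(5L, 40L)  # intercistronic gap for nonoverlapping operonic genes

  rng <- function(pair) if (pair[1] == pair[2]) pair[1] else
    sample(seq(pair[1], pair[2]), 1L)

  blocks <- list()
  genes <- list()   # per-gene records with block-local coords
  gid <- 0L
  for (op in seq_len(config@nOperons)) {
    ng <- rng(config@genesPerOperon)
    minusStrand <- runif(1) < config@reverseStrandFraction
    ncod <- vapply(seq_len(ng), function(i) rng(config@cdsLengthCodons), 1L)
    m1 <- sample(.BASES, ng, replace = TRUE, prob = config@minus1BaseWeights)
    ovl <- c(FALSE, runif(max(ng - 1L, 0L)) < config@overlapProbability)[seq_len(ng)]

    cs <- ce <- utr <- integer(ng)
    pos <- 1L
    for (j in seq_len(ng)) {
      if (j == 1L) {
        utr[j] <- rng(config@utr5Length)
        cs[j] <- pos + utr[j]
      } else if (ovl[j]) {
        utr[j] <- 0L
        cs[j] <- ce[j - 1L] - 3L
      } else {
        utr[j] <- rng(cisGap)
        cs[j] <- ce[j - 1L] + utr[j] + 1L
      }
      ce[j] <- cs[j] + 3L * ncod[j] - 1L
      pos <- ce[j] + 1L
    }
    blockLen <- ce[ng]
    chars <- sample(.BASES, blockLen, replace = TRUE)
    for (j in seq_len(ng)) {
      chars[cs[j]:(cs[j] + 2L)] <- c("A", "T", "G")
      # a gene whose successor overlaps it must end in TGA (shared with ATG)
      stopCodon <- if (j < ng && ovl[j + 1L]) c("T", "G", "A") else
        sample(list(c("T", "A", "A"), c("T", "A", "G"), c("T", "G", "A")), 1L)[[1]]
      chars[(ce[j] - 2L):ce[j]] <- stopCodon
      chars[cs[j] - 1L] <- m1[j]
      if (ovl[j])  # guard: keep the upstream penultimate codon (G, m1, A) non-stop
        chars[cs[j] - 2L] <- "G"
    }
    if (minusStrand) {
      comp <- c(A = "T", C = "G", G = "C", T = "A")
      chars <- rev(unname(comp[chars]))
      newcs <- blockLen - ce + 1L
      newce <- blockLen - cs + 1L
      cs <- newcs; ce <- newce
    }
    blocks[[op]] <- chars
    genes[[op]] <- data.frame(
      gene_id = sprintf("g%04d", gid + seq_len(ng)),
      operon_id = sprintf("op%04d", op),
      operon_rank = seq_len(ng),
      strand = if (minusStrand) "-" else "+",
      local_start = cs, local_end = ce,
      utr5_len = utr, minus1_base = m1, overlapping = ovl,
      cds_len = 3L * ncod,
      stringsAsFactors = FALSE)
    gid <- gid + ng
  }

  # lay blocks on the replicon with flanks and inter-operon gaps
  gaps <- vapply(seq_len(config@nOperons), function(i) rng(operonGap), 1L)
  offsets <- flank + cumsum(c(0L, vapply(blocks, length, 1L) + gaps))[seq_along(blocks)]
  needed <- flank + sum(vapply(blocks, length, 1L)) + sum(gaps) + flank
  if (!is.na(config@repliconLength) && config@repliconLength < needed)
    stop("infeasible packing: ", needed, " nt required but repliconLength is ",
         config@repliconLength)
  total <- max(needed, config@repliconLength, na.rm = TRUE)

  seqChars <- sample(.BASES, total, replace = TRUE)
  for (i in seq_along(blocks))
    seqChars[offsets[i] + seq_along(blocks[[i]])] <- blocks[[i]]

  tab <- do.call(rbind, genes)
  tab$start <- tab$local_start + rep(offsets, vapply(genes, nrow, 1L))
  tab$end <- tab$local_end + rep(offsets, vapply(genes, nrow, 1L))

  gr <- GenomicRanges::GRanges(
    seqnames = "chrSim",
    ranges = IRanges::IRanges(tab$start, tab$end),
    strand = tab$strand,
    gene_id = tab$gene_id,
    utr5_len = tab$utr5_len,
    operon_id = tab$operon_id,
    operon_rank = tab$operon_rank,
    minus1_base = tab$minus1_base,
    leaderless = FALSE,
    seqlengths = c(chrSim = total))
  gr <- categorizeGenes(gr)

  abundance <- rlnorm(nrow(tab), config@abundanceMeanlog, config@abundanceSdlog)
  escape <- unname(config@escapeProb[tab$minus1_base])
  escapeEff <- ifelse(tab$overlapping,
                      1 - (1 - escape) * config@couplingAttenuation, escape)
  truth <- data.frame(
    gene_id = tab$gene_id,
    minus1_base = tab$minus1_base,
    overlapping = tab$overlapping,
    category = gr$category,
    escape_true = escapeEff,
    abundance = abundance,
    stringsAsFactors = FALSE)

  seq <- Biostrings::DNAStringSet(paste(seqChars, collapse = ""))
  names(seq) <- "chrSim"
  new("SimGenome", sequence = seq, genes = gr, truth = truth)
}

#' Write simulated genome, annotation and truth to disk
#'
#' Emits \code{genome.fa}, \code{genes.gff3} (CDS features with
#' \code{locus_tag}), \code{operons.tsv} (gene_id, operon_id, rank) and
#' \code{truth.tsv}. Output is byte-identical for identical inputs.
#'
#' @param genome a [SimGenome-class].
#' @param dir output directory (created if absent).
#' @return Invisibly, the named vector of written paths.
#' @export
writeSimulation <- function(genome, dir) {
  stopifnot(is(genome, "SimGenome"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(fasta = file.path(dir, "genome.fa"),
             gff = file.path(dir, "genes.gff3"),
             operons = file.path(dir, "operons.tsv"),
             truth = file.path(dir, "truth.tsv"))
  Biostrings::writeXStringSet(genome@sequence, paths["fasta"])
  gr <- genome@genes
  out <- GenomicRanges::GRanges(GenomicRanges::seqnames(gr),
                                IRanges::ranges(gr), GenomicRanges::strand(gr))
  out$source <- "riboStart"
  out$type <- "CDS"
  out$phase <- 0L
  out$ID <- gr$gene_id
  out$locus_tag <- gr$gene_id
  out$utr5_len <- gr$utr5_len
  out$minus1_base <- gr$minus1_base
  rtracklayer::export(out, paths["gff"], format = "gff3")
  write.table(data.frame(gene_id = gr$gene_id, operon_id = gr$operon_id,
                         rank = gr$operon_rank),
              paths["operons"], sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(genome@truth, paths["truth"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(paths)
}

.senseCodonDraw <- function(n, m) {
  # A-site codon index in 0..m-1 with weight 1.5 on the start codon,
  # 1 on each later sense codon
  pStart <- 1.5 / (m + 0.5)
  atStart <- runif(n) < pStart
  codon <- 1L + as.integer(floor(runif(n) * (m - 1L)))
  codon[atStart] <- 0L
  codon
}

#' Simulate ribosome footprints
#'
#' Initiation events occur on each gene at a rate proportional to its
#' transcript abundance, and footprint counts are a snapshot of ribosome
#' occupancy: an initiation event whose ribosome traverses the ORF
#' contributes one footprint per sense codon (A-site position uniform over
#' the sense codons with a mild 1.5x weight on the start codon), whereas an
#' arrested ribosome occupies only the start codon. Under \code{"control"}
#' every event traverses. Under \code{"drug"}, an event arrests at the start
#' codon with probability \code{1 - escape} (escape depends on the gene's -1
#' base and is attenuated for start/stop-overlapping genes); an arrested
#' ribosome leaves a single start-codon footprint with probability
#' \code{stallRetainProb}, otherwise it dissociates and leaves none. The
#' expected drug/control ratio of ORF-body density for a gene therefore
#' equals its escape probability. Counts are Poisson with total control
#' expectation \code{riboDepth}; the drug library is smaller by the fraction
#' of emission lost to arrest, as in a real drug-treated sample before depth
#' normalization. The footprint's 3' end is placed 12 nt downstream of the
#' first base of the A-site codon; lengths are uniform over
#' \code{riboLenRange}.
#'
#' @param genome a [SimGenome-class] from [buildGenome()].
#' @param condition \code{"control"} or \code{"drug"}.
#' @param config the [SimConfig-class] used for the genome.
#' @param seed integer seed for this library (default derived from the config
#'   seed and condition).
#' @return A read table (data.frame with \code{qname}, \code{rname},
#'   \code{strand}, \code{pos} (1-based leftmost), \code{len}) suitable for
#'   [assignRiboDensity()] or [writeSam()].
#' @export
simulateRiboseq <- function(genome, condition = c("control", "drug"), config,
                            seed = NULL) {
  stopifnot(is(genome, "SimGenome"), is(config, "SimConfig"))
  condition <- match.arg(condition)
  if (length(genome@genes) == 0L) stop("empty genome")
  if (is.null(seed)) seed <- config@seed + if (condition == "control") 101L else 202L
  set.seed(seed)

  gr <- genome@genes
  tr <- genome@truth
  ab <- tr$abundance
  mCod <- GenomicRanges::width(gr) %/% 3L - 1L  # sense codons per gene
  # initiation rate prop. to abundance; a traversing event emits one footprint
  # per sense codon, so the control library totals riboDepth in expectation
  evRate <- config@riboDepth * ab / sum(ab * mCod)
  if (condition == "control") {
    nTrav <- rpois(length(ab), evRate * mCod)
    nStall <- integer(length(ab))
  } else {
    esc <- tr$escape_true
    nTrav <- rpois(length(ab), evRate * esc * mCod)
    nStall <- rpois(length(ab),
                    evRate * (1 - esc) * config@stallRetainProb)
  }
  g <- c(rep.int(seq_along(ab), nTrav), rep.int(seq_along(ab), nStall))
  n <- length(g)
  if (n == 0L)
    return(data.frame(qname = character(), rname = character(),
                      strand = character(), pos = integer(), len = integer()))
  codon <- c(.senseCodonDraw(sum(nTrav), mCod[rep.int(seq_along(ab), nTrav)]),
             integer(sum(nStall)))

  len <- if (config@riboLenRange[1] == config@riboLenRange[2])
    rep(config@riboLenRange[1], n) else
    sample(seq(config@riboLenRange[1], config@riboLenRange[2]), n, replace = TRUE)
  plus <- as.character(GenomicRanges::strand(gr))[g] == "+"
  aSite <- ifelse(plus,
                  GenomicRanges::start(gr)[g] + 3L * codon,
                  GenomicRanges::end(gr)[g] - 3L * codon)
  pos <- ifelse(plus, aSite + 12L - len + 1L, aSite - 12L)
  sl <- Biostrings::width(genome@sequence)[1]
  ok <- pos >= 1L & pos + len - 1L <= sl
  data.frame(qname = sprintf("rfp_%s_%07d", condition, seq_len(sum(ok))),
             rname = names(genome@sequence)[1],
             strand = ifelse(plus, "+", "-")[ok],
             pos = as.integer(pos[ok]), len = as.integer(len[ok]),
             stringsAsFactors = FALSE)
}

#' Simulate RNA-seq fragments
#'
#' Fragments are sampled uniformly along each transcript (5' UTR plus CDS),
#' proportionally to transcript abundance, with lengths uniform over
#' \code{rnaLenRange}. Abundances do not differ between conditions: drug
#' effects on mRNA levels are outside the model.
#'
#' @inheritParams simulateRiboseq
#' @param seed integer seed for this library.
#' @return A read table as in [simulateRiboseq()].
#' @export
simulateRnaseq <- function(genome, config, seed = NULL) {
  stopifnot(is(genome, "SimGenome"), is(config, "SimConfig"))
  if (length(genome@genes) == 0L) stop("empty genome")
  if (is.null(seed)) seed <- config@seed + 303L
  set.seed(seed)

  gr <- genome@genes
  ab <- genome@truth$abundance
  lambda <- config@rnaDepth * ab / sum(ab)
  nFr <- rpois(length(lambda), lambda)
  g <- rep.int(seq_along(nFr), nFr)
  n <- length(g)
  if (n == 0L)
    return(data.frame(qname = character(), rname = character(),
                      strand = character(), pos = integer(), len = integer()))

  plus <- as.character(GenomicRanges::strand(gr))[g] == "+"
  txStart <- ifelse(plus, GenomicRanges::start(gr)[g] - gr$utr5_len[g],
                    GenomicRanges::start(gr)[g])
  txEnd <- ifelse(plus, GenomicRanges::end(gr)[g],
                  GenomicRanges::end(gr)[g] + gr$utr5_len[g])
  tlen <- txEnd - txStart + 1L
  len <- if (config@rnaLenRange[1] == config@rnaLenRange[2])
    rep(config@rnaLenRange[1], n) else
    sample(seq(config@rnaLenRange[1], config@rnaLenRange[2]), n, replace = TRUE)
  len <- pmin(len, tlen)
  off <- as.integer(floor(runif(n) * (tlen - len + 1L)))
  pos <- txStart + off
  sl <- Biostrings::width(genome@sequence)[1]
  ok <- pos >= 1L & pos + len - 1L <= sl
  data.frame(qname = sprintf("rna_%07d", seq_len(sum(ok))),
             rname = names(genome@sequence)[1],
             strand = ifelse(plus, "+", "-")[ok],
             pos = as.integer(pos[ok]), len = as.integer(len[ok]),
             stringsAsFactors = FALSE)
}

#' Write a read table as single-end ungapped SAM
#'
#' Produces a valid SAM v1 file (header with \code{@SQ}, CIGAR
#' \code{<len>M}, flag 0/16, \code{NH:i:1}); sequences are taken from the
#' reference so records round-trip through any SAM-aware tool.
#'
#' @param reads read table from [simulateRiboseq()]/[simulateRnaseq()].
#' @param genome a [SimGenome-class] (source of reference names, lengths and
#'   read sequences).
#' @param path output file path.
#' @return Invisibly, \code{path}.
#' @export
writeSam <- function(reads, genome, path) {
  stopifnot(is(genome, "SimGenome"))
  sl <- Biostrings::width(genome@sequence)
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", names(genome@sequence), sl),
              "@PG\tID:riboStart\tPN:riboStart")
  if (nrow(reads) == 0L) {
    writeLines(header, path)
    return(invisible(path))
  }
  gseq <- as.character(genome@sequence[[1]])
  seqs <- substring(gseq, reads$pos, reads$pos + reads$len - 1L)
  recs <- paste(reads$qname,
                ifelse(reads$strand == "+", 0L, 16L),
                reads$rname, reads$pos, 255L,
                paste0(reads$len, "M"), "*", 0L, 0L,
                seqs, "*", "NH:i:1", sep = "\t")
  writeLines(c(header, recs), path)
  invisible(path)
}
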
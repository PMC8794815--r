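.asReads <- function(x, lengthFilter) {
  if (is.character(x) && length(x) == 1L) readAlignments(x, lengthFilter)
  else if (is.data.frame(x)) x
  else stop("reads must be a read table or a SAM/BED path")
}

.writeTsv <- function(df, path, params) {
  con <- file(path, "w")
  writeLines(c(sprintf("# riboStart %s", as.character(utils::packageVersion("riboStart"))),
               sprintf("# %s", params)), con)
  suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  close(con)
  invisible(path)
}

#' Run the full analysis on one treated/control pair
#'
#' Executes every stage in dependency order: density assignment, per-gene
#' quantification, TE change, top-fraction selection, start-codon context
#' enrichment, per-group comparisons (by -1 base with the top fraction
#' removed, and by coupling category), metagene profiles, head enrichment
#' and its change, and the rank correlation between head-enrichment and TE
#' changes.
#'
#' @param riboTreated,rnaTreated,riboControl,rnaControl read tables (from the
#'   simulator or [readAlignments()]) or SAM/BED paths.
#' @param genes annotation \code{GRanges} (e.g. from [readAnnotation()] or
#'   [geneModels()]).
#' @param genome replicon sequences (\code{DNAStringSet},
#'   [SimGenome-class], or a FASTA path) for context extraction.
#' @param fraction top-inhibited fraction (default 0.05).
#' @param alpha family-wise error rate of the motif threshold.
#' @param pseudocount RPKM pseudocount for [deltaTE()].
#' @param rnaRpkmFloor,riboCountFloor expression floor, see [quantifyGenes()].
#' @param riboLengthFilter,rnaLengthFilter read-length windows applied when
#'   reads are loaded from files.
#' @param contextWindow offsets of the context strings around the start codon.
#' @param metageneWindow,coverageFloor metagene settings, see
#'   [metageneProfile()].
#' @param heCoverageFloor minimum mean control CDS density (reads/nt) for a
#'   gene to enter the head-enrichment universe (the \code{he} table, the
#'   merged \code{log2_he_change} and the correlation). Position-level
#'   metrics averaged over a 15-nt head need markedly deeper coverage than
#'   gene-level counts, so this floor is stricter than the expression floor.
#' @param outdir if non-\code{NULL}, all result tables are written there as
#'   TSV with a commented parameter header, plus a run log.
#' @return A list: \code{quant_control}, \code{quant_treated}, \code{delta}
#'   (with \code{log2_he_change} merged in), \code{top_genes}, \code{motif},
#'   \code{groups_minus1}, \code{groups_category}, \code{metagene_control},
#'   \code{metagene_treated}, \code{he}, \code{spearman}.
#' @export
runAnalysis <- function(riboTreated, rnaTreated, riboControl, rnaControl,
                        genes, genome,
                        fraction = 0.05, alpha = 0.05, pseudocount = 0.1,
                        rnaRpkmFloor = 1, riboCountFloor = 32,
                        riboLengthFilter = c(20L, 45L),
                        rnaLengthFilter = c(25L, 45L),
                        contextWindow = c(-15L, 17L),
                        metageneWindow = c(-30L, 60L), coverageFloor = 0.1,
                        heCoverageFloor = 0.25, outdir = NULL) {
  seqs <- if (is.character(genome)) Biostrings::readDNAStringSet(genome)
    else if (is(genome, "SimGenome")) genomeSequence(genome) else genome
  names(seqs) <- sub("\\s.*", "", names(seqs))
  sl <- setNames(Biostrings::width(seqs), names(seqs))

  riboT <- assignRiboDensity(.asReads(riboTreated, riboLengthFilter), sl)
  riboC <- assignRiboDensity(.asReads(riboControl, riboLengthFilter), sl)
  rnaT <- assignRnaDensity(.asReads(rnaTreated, rnaLengthFilter), sl)
  rnaC <- assignRnaDensity(.asReads(rnaControl, rnaLengthFilter), sl)

  qt <- quantifyGenes(riboT, rnaT, genes, rnaRpkmFloor, riboCountFloor)
  qc <- quantifyGenes(riboC, rnaC, genes, rnaRpkmFloor, riboCountFloor)
  delta <- deltaTE(qt, qc, pseudocount, genes)
  top <- selectTopInhibited(delta, fraction)

  ctx <- extractContext(genes, seqs, contextWindow)
  universe <- intersect(delta$gene_id, names(ctx))
  fg <- intersect(top, universe)
  if (length(fg) < 5L) {
    # the binomial score needs a minimal foreground; widen to the 5 most
    # inhibited genes on small universes
    ord <- delta$gene_id[order(delta$log2_te_change, delta$gene_id)]
    fg <- head(intersect(ord, universe), 5L)
  }
  motif <- plogoScores(ctx[fg], ctx[universe], alpha, contextWindow)

  groupsMinus1 <- compareGroups(delta, by = "minus1_base",
                                test = "mann_whitney",
                                excludeTopFraction = fraction)
  groupsCategory <- compareGroups(delta, by = "category", test = "t_test")

  mgControl <- metageneProfile(riboC, genes, metageneWindow,
                               coverageFloor = coverageFloor)
  mgTreated <- metageneProfile(riboT, genes, metageneWindow,
                               coverageFloor = coverageFloor)

  heC <- suppressWarnings(headEnrichment(riboC, genes))
  heT <- suppressWarnings(headEnrichment(riboT, genes))
  heUniverse <- genes$gene_id[.geneSums(riboC, genes) /
                                GenomicRanges::width(genes) >= heCoverageFloor]
  he <- suppressMessages(deltaHeadEnrichment(
    heT[heT$gene_id %in% heUniverse, ], heC[heC$gene_id %in% heUniverse, ]))
  delta$log2_he_change <- he$log2_he_change[match(delta$gene_id, he$gene_id)]
  rho <- suppressWarnings(spearmanHeTe(delta))

  bundle <- list(quant_control = qc, quant_treated = qt, delta = delta,
                 top_genes = top, motif = motif,
                 groups_minus1 = groupsMinus1,
                 groups_category = groupsCategory,
                 metagene_control = mgControl, metagene_treated = mgTreated,
                 he = he, spearman = rho)

  if (!is.null(outdir)) {
    if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
    params <- sprintf(paste0("fraction=%g alpha=%g pseudocount=%g ",
                             "rnaRpkmFloor=%g riboCountFloor=%g ",
                             "coverageFloor=%g"),
                      fraction, alpha, pseudocount, rnaRpkmFloor,
                      riboCountFloor, coverageFloor)
    .writeTsv(qc, file.path(outdir, "quant_control.tsv"), params)
    .writeTsv(qt, file.path(outdir, "quant_treated.tsv"), params)
    .writeTsv(delta, file.path(outdir, "delta.tsv"), params)
    .writeTsv(data.frame(gene_id = top), file.path(outdir, "top_genes.tsv"),
              params)
    scores <- as.data.frame(t(motifScores(motif)))
    scores <- cbind(offset = motif@offsets, scores)
    .writeTsv(scores, file.path(outdir, "motif_scores.tsv"),
              sprintf("%s threshold=%g fg_n=%d", params,
                      motifThreshold(motif), motif@fgN))
    .writeTsv(groupsMinus1, file.path(outdir, "groups_minus1.tsv"), params)
    .writeTsv(groupsCategory, file.path(outdir, "groups_category.tsv"), params)
    .writeTsv(mgControl, file.path(outdir, "metagene_control.tsv"), params)
    .writeTsv(mgTreated, file.path(outdir, "metagene_treated.tsv"), params)
    .writeTsv(he, file.path(outdir, "head_enrichment.tsv"), params)
    writeLines(c(sprintf("riboStart %s",
                         as.character(utils::packageVersion("riboStart"))),
                 sprintf("spearman_rho=%g n=%d", rho$rho, rho$n),
                 params),
               file.path(outdir, "run_log.txt"))
  }
  bundle
}

#' Simulate and analyze end to end
#'
#' Builds a synthetic genome from \code{config}, simulates Ribo-seq and
#' RNA-seq libraries for the control and drug conditions, and runs
#' [runAnalysis()] on them. Deterministic given \code{config@seed}.
#'
#' @param config a [SimConfig-class].
#' @param outdir optional output directory passed to [runAnalysis()]; the
#'   simulated genome, annotation and truth are also written there.
#' @param ... further parameters for [runAnalysis()].
#' @return The [runAnalysis()] bundle, plus \code{genome} (the
#'   [SimGenome-class]).
#' @examples
#' \donttest{
#' res <- runAll(simConfig(nOperons = 40L, riboDepth = 4e4, rnaDepth = 4e4,
#'                         seed = 11L))
#' res$spearman$rho
#' }
#' @export
runAll <- function(config, outdir = NULL, ...) {
  stopifnot(is(config, "SimConfig"))
  genome <- buildGenome(config)
  riboC <- simulateRiboseq(genome, "control", config)
  riboT <- simulateRiboseq(genome, "drug", config)
  rnaC <- simulateRnaseq(genome, config, seed = config@seed + 303L)
  rnaT <- simulateRnaseq(genome, config, seed = config@seed + 404L)
  if (!is.null(outdir)) {
    if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
    writeSimulation(genome, outdir)
  }
  bundle <- runAnalysis(riboT, rnaT, riboC, rnaC,
                        genes = geneModels(genome), genome = genome,
                        outdir = outdir, ...)
  bundle$genome <- genome
  bundle
}
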
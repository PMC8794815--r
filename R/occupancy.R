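.cdsVector <- function(track, gene) {
  repl <- as.character(GenomicRanges::seqnames(gene))
  s <- as.character(GenomicRanges::strand(gene))
  v <- .windowVector(track, repl, s, GenomicRanges::start(gene),
                     GenomicRanges::end(gene))
  if (s == "-") rev(v) else v
}

#' Metagene profile of ribosome density around start codons
#'
#' For every qualifying gene, A-site density over a window anchored at the
#' first base of the start codon is divided by that gene's mean CDS density
#' (so the start-codon peak itself does not deflate the profile), and the
#' profile reports the median of these normalized values across genes at each
#' offset. Genes qualify when the window (plus a margin) fits inside the CDS
#' downstream and the replicon upstream, and the mean CDS density clears a
#' coverage floor.
#'
#' @param track [DensityTrack-class] of A-site density.
#' @param genes annotation \code{GRanges}.
#' @param window integer pair of offsets relative to the first base of the
#'   start codon (default -30..+60).
#' @param splitByMinus1 if \code{TRUE}, one profile per -1 base.
#' @param coverageFloor minimum mean CDS density (reads/nt) for inclusion.
#' @param margin extra CDS length (nt) required beyond the window's right
#'   edge.
#' @param pseudocount added to the per-gene normalization denominator.
#' @return A data.frame: \code{offset}, \code{value}, \code{n_genes},
#'   \code{group} (\code{"all"} or the -1 base).
#' @export
metageneProfile <- function(track, genes, window = c(-30L, 60L),
                            splitByMinus1 = FALSE, coverageFloor = 0.1,
                            margin = 9L, pseudocount = 0) {
  stopifnot(is(track, "DensityTrack"), window[1] < window[2])
  sl <- track@seqlengths
  repl <- as.character(GenomicRanges::seqnames(genes))
  s <- as.character(GenomicRanges::strand(genes))
  gStart <- GenomicRanges::start(genes)
  gEnd <- GenomicRanges::end(genes)
  longEnough <- GenomicRanges::width(genes) >= window[2] + margin
  inBounds <- ifelse(s == "+",
                     gStart + window[1] >= 1L & gStart + window[2] <= sl[repl],
                     gEnd - window[2] >= 1L & gEnd - window[1] <= sl[repl])
  meanDens <- .geneSums(track, genes) / GenomicRanges::width(genes)
  keep <- which(longEnough & inBounds & meanDens >= coverageFloor)
  if (!length(keep))
    stop("no gene passes the metagene filters (CDS length >= ",
         window[2] + margin, " nt, mean CDS density >= ", coverageFloor, ")")

  w <- window[2] - window[1] + 1L
  mat <- matrix(NA_real_, nrow = length(keep), ncol = w)
  for (j in seq_along(keep)) {
    i <- keep[j]
    v <- if (s[i] == "+")
      .windowVector(track, repl[i], "+", gStart[i] + window[1],
                    gStart[i] + window[2])
    else
      rev(.windowVector(track, repl[i], "-", gEnd[i] - window[2],
                        gEnd[i] - window[1]))
    mat[j, ] <- v / (meanDens[i] + pseudocount)
  }
  offsets <- seq(window[1], window[2])
  groups <- if (splitByMinus1) genes$minus1_base[keep] else rep("all", length(keep))
  out <- lapply(unique(groups), function(gp) {
    rows <- groups == gp
    data.frame(offset = offsets,
               value = apply(mat[rows, , drop = FALSE], 2, median),
               n_genes = sum(rows), group = gp, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Head enrichment of ribosome density
#'
#' The head enrichment of a gene is the mean A-site density over the
#' start-proximal "head" region (default: the first five codons, CDS nt
#' 0-14) relative to the mean density across the ORF body (default: nt 15 up
#' to 9 nt before the CDS end, excluding the stop-codon region), each offset
#' by a pseudocount:
#' \code{HE = (mean(head) + p) / (mean(body) + p)}.
#' The pseudocount is expressed as a fraction of the gene's mean CDS density
#' (\code{p = pseudocount * mean CDS density}), which makes HE invariant
#' under rescaling of the whole track -- i.e. independent of sequencing
#' depth -- for every pseudocount value, not only at 0. A gene with no CDS
#' density at all gets HE = 1 (no evidence either way). Genes too short to
#' contain disjoint head and body regions are skipped with a warning.
#'
#' @param track [DensityTrack-class] of A-site density.
#' @param genes annotation \code{GRanges}.
#' @param headWindow inclusive 0-based nt offsets of the head within the CDS.
#' @param bodyStart first 0-based nt offset of the body.
#' @param bodyEndTrim nt excluded from the CDS 3' end (stop region).
#' @param pseudocount additive constant keeping HE positive and finite,
#'   as a fraction of the gene's mean CDS density.
#' @return A data.frame: \code{gene_id}, \code{he}.
#' @export
headEnrichment <- function(track, genes, headWindow = c(0L, 14L),
                           bodyStart = 15L, bodyEndTrim = 9L,
                           pseudocount = 0.01) {
  stopifnot(is(track, "DensityTrack"))
  len <- GenomicRanges::width(genes)
  ok <- len >= bodyStart + bodyEndTrim + 1L & headWindow[2] < len
  if (any(!ok))
    warning(sum(!ok), " gene(s) too short for disjoint head/body skipped")
  he <- vapply(which(ok), function(i) {
    v <- .cdsVector(track, genes[i])
    headMean <- mean(v[(headWindow[1] + 1L):(headWindow[2] + 1L)])
    bodyMean <- mean(v[(bodyStart + 1L):(len[i] - bodyEndTrim)])
    p <- pseudocount * mean(v)
    if (headMean == 0 && bodyMean == 0) return(1)
    (headMean + p) / (bodyMean + p)
  }, numeric(1))
  data.frame(gene_id = genes$gene_id[ok], he = he, stringsAsFactors = FALSE)
}

#' Drug-induced change in head enrichment
#'
#' @param treated,control head-enrichment tables from [headEnrichment()].
#' @return A data.frame: \code{gene_id}, \code{he_control},
#'   \code{he_treated}, \code{log2_he_change}. Genes absent from either
#'   condition are excluded with a message. Swapping the arguments negates
#'   every change.
#' @export
deltaHeadEnrichment <- function(treated, control) {
  shared <- intersect(treated$gene_id, control$gene_id)
  dropped <- length(union(treated$gene_id, control$gene_id)) - length(shared)
  if (dropped > 0)
    message(dropped, " gene(s) missing from one condition excluded")
  t <- treated$he[match(shared, treated$gene_id)]
  c <- control$he[match(shared, control$gene_id)]
  data.frame(gene_id = shared, he_control = c, he_treated = t,
             log2_he_change = log2(t / c), stringsAsFactors = FALSE)
}

#' Spearman correlation between head-enrichment and TE changes
#'
#' Rank correlation (average ranks for ties) between per-gene
#' \code{log2_he_change} and \code{log2_te_change}. A negative coefficient
#' means genes accumulating more ribosomes at their start codon under the
#' drug lose more translation efficiency.
#'
#' @param delta a table carrying finite \code{log2_te_change} and
#'   \code{log2_he_change} columns for at least 3 genes.
#' @return A list with \code{rho} and \code{n}.
#' @export
spearmanHeTe <- function(delta) {
  ok <- is.finite(delta$log2_te_change) & is.finite(delta$log2_he_change)
  n <- sum(ok)
  if (n < 3L) stop("need at least 3 genes with finite values, got ", n)
  list(rho = cor(delta$log2_he_change[ok], delta$log2_te_change[ok],
                 method = "spearman"),
       n = n)
}
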
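#' Extract start-codon context sequences
#'
#' Returns, per gene, the genomic sequence over a fixed window of offsets
#' relative to the first base of the start codon (default -15..+17, a 33-nt
#' string whose offsets 0..2 are the start codon). Minus-strand genes are
#' reverse-complemented so the string always reads 5' to 3' on the coding
#' strand; the context is genomic, so short 5' UTRs are padded by upstream
#' replicon sequence. Genes whose window exits the replicon are dropped with
#' a warning.
#'
#' @param genes annotation \code{GRanges}.
#' @param genome a [SimGenome-class] or \code{DNAStringSet} of replicons.
#' @param window integer pair of offsets around the first CDS base.
#' @return Named character vector of fixed-width context strings.
#' @export
extractContext <- function(genes, genome, window = c(-15L, 17L)) {
  seqs <- if (is(genome, "SimGenome")) genome@sequence else genome
  stopifnot(is(seqs, "DNAStringSet"))
  sl <- setNames(Biostrings::width(seqs), names(seqs))
  repl <- as.character(GenomicRanges::seqnames(genes))
  s <- as.character(GenomicRanges::strand(genes))
  from <- ifelse(s == "+", GenomicRanges::start(genes) + window[1],
                 GenomicRanges::end(genes) - window[2])
  to <- ifelse(s == "+", GenomicRanges::start(genes) + window[2],
               GenomicRanges::end(genes) - window[1])
  ok <- from >= 1L & to <= sl[repl]
  if (any(!ok))
    warning(sum(!ok), " gene(s) with context window outside the replicon dropped")
  ctx <- vapply(which(ok), function(i) {
    x <- Biostrings::subseq(seqs[[repl[i]]], from[i], to[i])
    if (s[i] == "-") x <- Biostrings::reverseComplement(x)
    as.character(x)
  }, character(1))
  names(ctx) <- genes$gene_id[ok]
  ctx
}

.contextCounts <- function(ctx, width) {
  m <- matrix(unlist(strsplit(ctx, "")), ncol = width, byrow = TRUE)
  vapply(seq_len(width), function(j) {
    tabulate(factor(m[, j], levels = .BASES), nbins = 4L)
  }, integer(4))  # 4 x width, rows A,C,G,T
}

#' Position-specific binomial enrichment of a foreground set
#'
#' For each window position and base, compares the foreground count k (out of
#' n foreground genes) with the background frequency q of that base at that
#' position. When k/n >= q the score is \code{-log10 Pr[Binomial(n, q) >= k]}
#' (overrepresentation, positive); otherwise it is
#' \code{log10 Pr[Binomial(n, q) <= k]} (underrepresentation, negative).
#' The significance line is Bonferroni-corrected over all 4 x width tests:
#' \code{threshold = -log10(alpha / (4 * width))}. Tails are computed via the
#' binomial survival function, which is numerically stable for large n.
#'
#' @param foreground character vector of fixed-width context strings (e.g.
#'   the most drug-inhibited genes), at least 5.
#' @param background context strings of the analysis universe (e.g. all
#'   expressed genes); per-position background frequencies are used because
#'   start-proximal composition is position-structured (Shine-Dalgarno).
#' @param alpha family-wise error rate for the threshold.
#' @param window integer pair of offsets the strings span (labels only).
#' @return A [MotifResult-class].
#' @export
plogoScores <- function(foreground, background, alpha = 0.05,
                        window = c(-15L, 17L)) {
  if (length(foreground) < 5L)
    stop("foreground must contain at least 5 sequences")
  width <- unique(nchar(c(foreground, background)))
  if (length(width) != 1L) stop("context strings must share one width")
  n <- length(foreground)
  k <- .contextCounts(foreground, width)
  bg <- .contextCounts(background, width)
  q <- sweep(bg, 2, colSums(bg), "/")

  over <- k / n >= q
  score <- matrix(0, 4L, width, dimnames = list(.BASES, NULL))
  # upper tail: Pr[X >= k] = survival at k - 1
  score[over] <- -log10(pbinom(k[over] - 1L, n, q[over], lower.tail = FALSE))
  score[!over] <- log10(pbinom(k[!over], n, q[!over]))
  degenerate <- q == 0 & k > 0
  if (any(degenerate)) {
    warning(sum(degenerate),
            " cell(s) with zero background frequency but nonzero foreground",
            " count capped")
    score[degenerate] <- -log10(.Machine$double.xmin)
  }
  offsets <- seq(window[1], window[2])
  if (length(offsets) != width) offsets <- seq_len(width)
  colnames(score) <- colnames(q) <- as.character(offsets)
  new("MotifResult", score = score,
      threshold = -log10(alpha / (4 * width)),
      fgN = as.integer(n), bgFreqs = q,
      offsets = as.integer(offsets), alpha = alpha)
}
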
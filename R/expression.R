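#' Drug-induced translation-efficiency changes
#'
#' For every gene expressed in the control condition, computes
#' \deqn{\Delta TE = \log_2\frac{ribo\_rpkm_t + p}{rna\_rpkm_t + p}
#'                 - \log_2\frac{ribo\_rpkm_c + p}{rna\_rpkm_c + p}}
#' with pseudocount \code{p} applied on the RPKM scale so the change stays
#' finite at zero coverage. Genes failing the control expression floor are
#' excluded.
#'
#' @param treated,control gene tables from [quantifyGenes()] on the same
#'   annotation.
#' @param pseudocount RPKM-scale pseudocount (default 0.1); 0 reproduces the
#'   hard-filtered ratio.
#' @param genes optional annotation \code{GRanges}; when supplied,
#'   \code{minus1_base} and \code{category} columns are attached.
#' @return A data.frame (\code{gene_id}, \code{log2_te_change}, plus
#'   annotation columns when available).
#' @export
deltaTE <- function(treated, control, pseudocount = 0.1, genes = NULL) {
  if (!identical(sort(treated$gene_id), sort(control$gene_id))) {
    diff <- c(setdiff(treated$gene_id, control$gene_id),
              setdiff(control$gene_id, treated$gene_id))
    stop("gene sets differ between conditions: ",
         paste(head(diff, 10), collapse = ", "),
         if (length(diff) > 10) ", ...")
  }
  control <- control[match(treated$gene_id, control$gene_id), ]
  p <- pseudocount
  d <- log2((treated$ribo_rpkm + p) / (treated$rna_rpkm + p)) -
       log2((control$ribo_rpkm + p) / (control$rna_rpkm + p))
  out <- data.frame(gene_id = treated$gene_id,
                    log2_te_change = d,
                    stringsAsFactors = FALSE)[control$expressed, , drop = FALSE]
  if (!is.null(genes)) {
    i <- match(out$gene_id, genes$gene_id)
    out$minus1_base <- genes$minus1_base[i]
    out$category <- genes$category[i]
  }
  rownames(out) <- NULL
  out
}

#' Select the most drug-inhibited genes
#'
#' Returns the \code{k} genes with the most negative TE change, where
#' \code{k = round(fraction * n)} using round-half-away-from-zero (so 5\% of
#' 2,057 genes selects 103), with \code{k >= 1}. Ties at the boundary are
#' broken by \code{gene_id} lexicographic order, making the selection
#' deterministic.
#'
#' @param delta a table from [deltaTE()] with finite \code{log2_te_change}.
#' @param fraction fraction of genes to select, in (0, 1).
#' @return Character vector of selected \code{gene_id}s.
#' @export
selectTopInhibited <- function(delta, fraction = 0.05) {
  if (nrow(delta) == 0L) stop("empty delta table")
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  if (any(!is.finite(delta$log2_te_change)))
    stop("log2_te_change must be finite; apply a pseudocount or filter first")
  n <- nrow(delta)
  k <- max(1L, as.integer(floor(fraction * n + 0.5)))
  ord <- order(delta$log2_te_change, delta$gene_id)
  delta$gene_id[ord][seq_len(k)]
}

.pairTest <- function(x, y, test) {
  if (test == "mann_whitney") {
    exact <- length(x) <= 8 && length(y) <= 8 && !anyDuplicated(c(x, y))
    suppressWarnings(wilcox.test(x, y, exact = exact)$p.value)
  } else {
    t.test(x, y)$p.value  # Welch
  }
}

#' Pairwise group comparisons of TE changes
#'
#' Runs all pairwise two-sided tests between groups of genes defined by the
#' -1 base or the coupling category, with Bonferroni adjustment over the
#' number of pairs. The Mann-Whitney U test is exact for group sizes up to 8
#' without ties and uses the tie-corrected normal approximation otherwise;
#' the t test is Welch's. Optionally removes the most-inhibited top fraction
#' first, so the comparison describes the bulk of the translatome rather than
#' the extreme tail.
#'
#' @param delta table from [deltaTE()].
#' @param by grouping column, \code{"minus1_base"} or \code{"category"}.
#' @param test \code{"mann_whitney"} or \code{"t_test"}.
#' @param value column holding the quantity compared.
#' @param excludeTopFraction if non-\code{NULL}, genes selected by
#'   [selectTopInhibited()] at this fraction are removed before testing.
#' @return A data.frame with one row per pair: group labels, sizes, medians,
#'   raw and Bonferroni-adjusted p values.
#' @export
compareGroups <- function(delta, by = c("minus1_base", "category"),
                          test = c("mann_whitney", "t_test"),
                          value = "log2_te_change",
                          excludeTopFraction = NULL) {
  by <- match.arg(by)
  test <- match.arg(test)
  if (!by %in% names(delta)) stop("delta lacks a '", by, "' column")
  if (!is.null(excludeTopFraction)) {
    top <- selectTopInhibited(delta, excludeTopFraction)
    delta <- delta[!delta$gene_id %in% top, , drop = FALSE]
  }
  groups <- split(delta[[value]], delta[[by]])
  groups <- lapply(groups, function(v) v[is.finite(v)])
  small <- vapply(groups, length, 1L) < 2L
  if (any(small)) {
    warning("group(s) with < 2 members skipped: ",
            paste(names(groups)[small], collapse = ", "))
    groups <- groups[!small]
  }
  if (length(groups) < 2L) stop("need at least two groups with >= 2 members")
  pairs <- utils::combn(names(groups), 2L)
  nPairs <- ncol(pairs)
  res <- lapply(seq_len(nPairs), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    p <- .pairTest(groups[[a]], groups[[b]], test)
    data.frame(group1 = a, group2 = b,
               n1 = length(groups[[a]]), n2 = length(groups[[b]]),
               median1 = median(groups[[a]]), median2 = median(groups[[b]]),
               p_value = p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$p_adjusted <- pmin(1, res$p_value * nPairs)
  res$test <- test
  res
}
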
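#' Categorize operonic genes by translational-coupling geometry
#'
#' Assigns each gene exactly one of three categories: \code{"other"} for
#' single-gene transcription units and the first genes of operons;
#' \code{"overlapping_operonic"} for downstream operonic genes whose start
#' codon's first base lies at or before the last base of the upstream gene's
#' stop codon (at least 1 nt of overlap, or a start codon fully upstream of
#' the stop) -- the geometry under which translational coupling by
#' reinitiation is strongest; \code{"nonoverlapping_operonic"} for all other
#' downstream operonic genes. Exactly adjacent codons (0-nt gap) are
#' nonoverlapping.
#'
#' @param genes annotation \code{GRanges} with \code{operon_id} and
#'   \code{operon_rank} metadata; genes of one operon must share a strand and
#'   have contiguous ranks starting at 1.
#' @return The same \code{GRanges} with a \code{category} column filled.
#' @export
categorizeGenes <- function(genes) {
  if (is.null(genes$operon_id) || is.null(genes$operon_rank))
    stop("annotation lacks operon_id/operon_rank; supply an operon table")
  category <- rep("other", length(genes))
  ranks <- split(seq_along(genes), genes$operon_id)
  s <- as.character(GenomicRanges::strand(genes))
  for (idx in ranks) {
    r <- genes$operon_rank[idx]
    if (!setequal(r, seq_along(idx)))
      stop("operon ", genes$operon_id[idx[1]], ": ranks not contiguous from 1")
    if (length(unique(s[idx])) != 1L)
      stop("operon ", genes$operon_id[idx[1]], ": genes on different strands")
    idx <- idx[order(r)]
    for (j in seq_along(idx)[-1]) {
      dn <- idx[j]; up <- idx[j - 1L]
      overlapping <- if (s[dn] == "+")
        GenomicRanges::start(genes)[dn] <= GenomicRanges::end(genes)[up]
      else
        GenomicRanges::end(genes)[dn] >= GenomicRanges::start(genes)[up]
      category[dn] <- if (overlapping) "overlapping_operonic"
        else "nonoverlapping_operonic"
    }
  }
  genes$category <- category
  genes
}
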
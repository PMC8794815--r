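.resolveSeqlengths <- function(x) {
  if (is(x, "SimGenome"))
    return(setNames(as.integer(Biostrings::width(x@sequence)),
                    names(x@sequence)))
  if (is.numeric(x) && !is.null(names(x)))
    return(setNames(as.integer(x), names(x)))
  stop("seqlengths must be a named integer vector or a SimGenome")
}

.emptyTracks <- function(seqlengths) {
  lapply(setNames(nm = names(seqlengths)), function(r)
    list("+" = S4Vectors::Rle(0, seqlengths[[r]]),
         "-" = S4Vectors::Rle(0, seqlengths[[r]])))
}

#' A-site ribosome density from footprint alignments
#'
#' Each accepted footprint contributes a unit mass at the first base of its
#' A-site codon, obtained by taking the read's 3' end and shifting 12 nt
#' against the direction of transcription: on the plus strand the position is
#' \code{pos + len - 1 - 12}, on the minus strand \code{pos + 12} (1-based).
#' Reads whose shifted position falls off the replicon are dropped with a
#' warning; the track's total mass equals the number of reads placed.
#'
#' @param reads read table from [readAlignments()] or the simulator.
#' @param seqlengths named replicon lengths, or a [SimGenome-class].
#' @return A [DensityTrack-class] of kind \code{"ribo_Asite"}.
#' @export
assignRiboDensity <- function(reads, seqlengths) {
  sl <- .resolveSeqlengths(seqlengths)
  if (nrow(reads) > 0 && !all(reads$rname %in% names(sl)))
    stop("reads reference unknown replicon(s)")
  plus <- reads$strand == "+"
  aSite <- ifelse(plus, reads$pos + reads$len - 1L - 12L, reads$pos + 12L)
  ok <- aSite >= 1L & aSite <= sl[reads$rname]
  if (any(!ok))
    warning(sum(!ok), " read(s) with off-replicon A-site position dropped")
  tracks <- .emptyTracks(sl)
  for (r in unique(reads$rname[ok])) {
    for (s in c("+", "-")) {
      i <- ok & reads$rname == r & reads$strand == s
      if (!any(i)) next
      tracks[[r]][[s]] <- IRanges::coverage(
        IRanges::IRanges(aSite[i], width = 1L), width = sl[[r]])
    }
  }
  new("DensityTrack", kind = "ribo_Asite", mass = as.numeric(sum(ok)),
      tracks = tracks, seqlengths = sl)
}

#' Fractional RNA-seq coverage
#'
#' An N-nt read contributes 1/N at each of the N bases it covers, so every
#' accepted read carries total mass exactly 1 and the track mass equals the
#' accepted read count. Reads extending beyond the replicon are an input
#' error (no clipping is performed).
#'
#' @inheritParams assignRiboDensity
#' @return A [DensityTrack-class] of kind \code{"rna_fractional"}.
#' @export
assignRnaDensity <- function(reads, seqlengths) {
  sl <- .resolveSeqlengths(seqlengths)
  if (nrow(reads) > 0 && !all(reads$rname %in% names(sl)))
    stop("reads reference unknown replicon(s)")
  if (nrow(reads) > 0 &&
      any(reads$pos < 1L | reads$pos + reads$len - 1L > sl[reads$rname]))
    stop("read(s) extend beyond the replicon: input error")
  tracks <- .emptyTracks(sl)
  for (r in unique(reads$rname)) {
    for (s in c("+", "-")) {
      i <- reads$rname == r & reads$strand == s
      if (!any(i)) next
      tracks[[r]][[s]] <- IRanges::coverage(
        IRanges::IRanges(reads$pos[i], width = reads$len[i]),
        width = sl[[r]], weight = 1 / reads$len[i])
    }
  }
  new("DensityTrack", kind = "rna_fractional", mass = as.numeric(nrow(reads)),
      tracks = tracks, seqlengths = sl)
}

.geneSums <- function(track, genes) {
  out <- numeric(length(genes))
  repl <- as.character(GenomicRanges::seqnames(genes))
  std <- as.character(GenomicRanges::strand(genes))
  sl <- track@seqlengths
  if (any(GenomicRanges::start(genes) < 1L) ||
      any(GenomicRanges::end(genes) > sl[repl]))
    stop("gene(s) outside replicon bounds")
  for (r in unique(repl)) {
    for (s in c("+", "-")) {
      idx <- which(repl == r & std == s)
      if (!length(idx)) next
      v <- IRanges::Views(track@tracks[[r]][[s]],
                          GenomicRanges::start(genes)[idx],
                          GenomicRanges::end(genes)[idx])
      out[idx] <- IRanges::viewSums(v)
    }
  }
  out
}

# density over [from, to] on one strand, as a plain vector
.windowVector <- function(track, replicon, strand, from, to) {
  as.numeric(S4Vectors::window(track@tracks[[replicon]][[strand]], from, to))
}

#' Per-gene counts, RPKM and translation efficiency
#'
#' Sums A-site ribosome density and fractional RNA coverage over each CDS,
#' converts to RPKM (reads per kilobase per million mapped reads, using the
#' track mass as the library size) and forms the translation efficiency
#' TE = ribo_rpkm / rna_rpkm. A gene is flagged \code{expressed} when its
#' RNA RPKM and ribosome footprint count clear the configurable floors; TE is
#' \code{NA} below the RNA floor.
#'
#' @param ribo [DensityTrack-class] of kind \code{"ribo_Asite"}.
#' @param rna [DensityTrack-class] of kind \code{"rna_fractional"}.
#' @param genes annotation \code{GRanges} (CDS intervals, \code{gene_id}).
#' @param rnaRpkmFloor,riboCountFloor expression floor: a gene is expressed
#'   when \code{rna_rpkm >= rnaRpkmFloor} and \code{ribo_count >=
#'   riboCountFloor}.
#' @return A data.frame: \code{gene_id}, \code{cds_len}, \code{ribo_count},
#'   \code{rna_count}, \code{ribo_rpkm}, \code{rna_rpkm}, \code{te},
#'   \code{expressed}.
#' @export
quantifyGenes <- function(ribo, rna, genes, rnaRpkmFloor = 1,
                          riboCountFloor = 32) {
  stopifnot(is(ribo, "DensityTrack"), is(rna, "DensityTrack"))
  if (ribo@mass == 0 || rna@mass == 0) stop("empty library")
  riboCount <- .geneSums(ribo, genes)
  rnaCount <- .geneSums(rna, genes)
  len <- GenomicRanges::width(genes)
  riboRpkm <- riboCount / ((len / 1e3) * (ribo@mass / 1e6))
  rnaRpkm <- rnaCount / ((len / 1e3) * (rna@mass / 1e6))
  te <- ifelse(rnaRpkm >= rnaRpkmFloor, riboRpkm / rnaRpkm, NA_real_)
  data.frame(gene_id = genes$gene_id,
             cds_len = len,
             ribo_count = riboCount,
             rna_count = rnaCount,
             ribo_rpkm = riboRpkm,
             rna_rpkm = rnaRpkm,
             te = te,
             expressed = rnaRpkm >= rnaRpkmFloor & riboCount >= riboCountFloor,
             stringsAsFactors = FALSE)
}

#' Relative ribosome occupancy along one gene
#'
#' A-site density over the gene window (5' UTR, CDS and stop codon) divided
#' by the gene's mRNA abundance (RNA-seq RPKM) and multiplied by the
#' condition's global residual-translation fraction (e.g. measured by
#' metabolic labeling; 1 for untreated cells). Returned 5' to 3' in
#' transcription direction, named by offset relative to the first base of the
#' start codon.
#'
#' @param ribo [DensityTrack-class] of A-site density.
#' @param gene single-row annotation \code{GRanges}.
#' @param rnaRpkm the gene's RNA-seq RPKM (> 0).
#' @param globalFactor residual-translation fraction in (0, 1].
#' @param utr5Len 5' UTR length; default from the annotation.
#' @return Named numeric vector of occupancy values.
#' @export
relativeOccupancy <- function(ribo, gene, rnaRpkm, globalFactor = 1,
                              utr5Len = NULL) {
  stopifnot(is(ribo, "DensityTrack"), length(gene) == 1L)
  if (is.null(utr5Len)) utr5Len <- gene$utr5_len
  if (is.na(utr5Len)) utr5Len <- 0L
  if (!is.numeric(rnaRpkm) || rnaRpkm <= 0)
    stop("relative occupancy undefined: rnaRpkm must be > 0")
  if (globalFactor <= 0 || globalFactor > 1)
    stop("globalFactor must lie in (0, 1]")
  repl <- as.character(GenomicRanges::seqnames(gene))
  s <- as.character(GenomicRanges::strand(gene))
  if (s == "+") {
    v <- .windowVector(ribo, repl, s,
                       GenomicRanges::start(gene) - utr5Len,
                       GenomicRanges::end(gene))
  } else {
    v <- rev(.windowVector(ribo, repl, s,
                           GenomicRanges::start(gene),
                           GenomicRanges::end(gene) + utr5Len))
  }
  occ <- v / rnaRpkm * globalFactor
  names(occ) <- seq(-utr5Len, GenomicRanges::width(gene) - 1L)
  occ
}
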
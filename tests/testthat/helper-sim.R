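# small, fast simulation settings used across tests
smallConfig <- function(...) {
  args <- list(...)
  defaults <- list(nOperons = 10L, riboDepth = 2e4, rnaDepth = 2e4,
                   seed = 42L)
  do.call(simConfig, utils::modifyList(defaults, args))
}

# a uniform-density track over one replicon, built directly
uniformTrack <- function(len, value = 1, kind = "ribo_Asite",
                         mass = len * value, replicon = "chr") {
  tracks <- list(list("+" = S4Vectors::Rle(value, len),
                      "-" = S4Vectors::Rle(value, len)))
  names(tracks) <- replicon
  new("DensityTrack", kind = kind, mass = mass, tracks = tracks,
      seqlengths = setNames(as.integer(len), replicon))
}

# track from explicit per-base vectors
vectorTrack <- function(plus, minus = numeric(length(plus)), mass = sum(plus) + sum(minus),
                        kind = "ribo_Asite", replicon = "chr") {
  tracks <- list(list("+" = S4Vectors::Rle(plus), "-" = S4Vectors::Rle(minus)))
  names(tracks) <- replicon
  new("DensityTrack", kind = kind, mass = mass, tracks = tracks,
      seqlengths = setNames(length(plus), replicon))
}

# minimal annotation GRanges
makeGenes <- function(starts, ends, strand = "+", replicon = "chr",
                      seqlen = max(ends) + 200L, ids = NULL, ...) {
  n <- length(starts)
  gr <- GenomicRanges::GRanges(
    replicon, IRanges::IRanges(starts, ends), strand,
    gene_id = if (is.null(ids)) sprintf("t%03d", seq_len(n)) else ids,
    seqlengths = setNames(as.integer(seqlen), replicon))
  extra <- list(...)
  for (nm in names(extra)) S4Vectors::mcols(gr)[[nm]] <- extra[[nm]]
  if (is.null(gr$utr5_len)) gr$utr5_len <- 20L
  gr
}

# minimal quant table row constructor
quantRow <- function(gene_id, ribo_rpkm, rna_rpkm, expressed = TRUE) {
  data.frame(gene_id = gene_id, ribo_rpkm = ribo_rpkm, rna_rpkm = rna_rpkm,
             expressed = expressed, stringsAsFactors = FALSE)
}
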
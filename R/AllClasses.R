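#' @import methods
#' @importClassesFrom Biostrings DNAStringSet
#' @importClassesFrom GenomicRanges GRanges
#' @importFrom stats median rlnorm rpois runif cor pbinom t.test wilcox.test setNames
#' @importFrom utils write.table read.table head
NULL

.BASES <- c("A", "C", "G", "T")

#' Simulation configuration
#'
#' Parameters of the generative model used by [buildGenome()],
#' [simulateRiboseq()] and [simulateRnaseq()]: an operon-structured bacterial
#' replicon whose genes differ in the nucleotide immediately preceding the
#' start codon (the -1 base), and a drug condition in which an initiation
#' event arrests at the start codon with a probability that depends on that
#' base. Arrested ribosomes leave a start-codon footprint with probability
#' \code{stallRetainProb}, otherwise they dissociate and leave none.
#' Downstream genes whose start codon overlaps the upstream stop codon
#' (translationally coupled reinitiation) have their arrest probability
#' multiplied by \code{couplingAttenuation}.
#'
#' @slot nOperons number of operons on the replicon.
#' @slot genesPerOperon integer pair: range of genes per operon.
#' @slot cdsLengthCodons integer pair: CDS length range in codons (incl. stop).
#' @slot utr5Length integer pair: 5' UTR length range in nt.
#' @slot overlapProbability probability that a non-first operonic gene's start
#'   codon overlaps the upstream stop codon.
#' @slot minus1BaseWeights named probabilities over A/C/G/T for the -1 base.
#' @slot escapeProb named probabilities over A/C/G/T: fraction of drug-exposed
#'   initiation events that escape arrest, per -1 base.
#' @slot couplingAttenuation factor in [0,1] multiplying the arrest
#'   probability of overlapping downstream genes.
#' @slot stallRetainProb probability an arrested ribosome leaves a
#'   start-codon footprint rather than dissociating.
#' @slot riboDepth,rnaDepth expected event/fragment counts per condition.
#' @slot riboLenRange,rnaLenRange integer pairs, read lengths in nt.
#' @slot abundanceMeanlog,abundanceSdlog lognormal parameters of per-gene
#'   transcript abundance.
#' @slot reverseStrandFraction fraction of operons placed on the minus strand.
#' @slot repliconLength optional fixed replicon length (NA = sized to fit);
#'   too small a value is an error.
#' @slot seed integer seed; identical configurations reproduce output
#'   bit-identically.
#' @export
setClass("SimConfig", representation(
  nOperons = "integer",
  genesPerOperon = "integer",
  cdsLengthCodons = "integer",
  utr5Length = "integer",
  overlapProbability = "numeric",
  minus1BaseWeights = "numeric",
  escapeProb = "numeric",
  couplingAttenuation = "numeric",
  stallRetainProb = "numeric",
  riboDepth = "numeric",
  rnaDepth = "numeric",
  riboLenRange = "integer",
  rnaLenRange = "integer",
  abundanceMeanlog = "numeric",
  abundanceSdlog = "numeric",
  reverseStrandFraction = "numeric",
  repliconLength = "integer",
  seed = "integer"
))

.checkPair <- function(x, what, minimum = 1L) {
  if (length(x) != 2L || any(is.na(x)) || x[1] > x[2] || x[1] < minimum)
    return(sprintf("'%s' must be an ordered integer pair with min >= %d", what, minimum))
  NULL
}

.checkProb <- function(x, what) {
  if (any(is.na(x)) || any(x < 0) || any(x > 1))
    return(sprintf("'%s' must lie in [0, 1]", what))
  NULL
}

setValidity("SimConfig", function(object) {
  msgs <- c(
    .checkPair(object@genesPerOperon, "genesPerOperon"),
    .checkPair(object@cdsLengthCodons, "cdsLengthCodons", 10L),
    .checkPair(object@utr5Length, "utr5Length"),
    .checkPair(object@riboLenRange, "riboLenRange", 15L),
    .checkPair(object@rnaLenRange, "rnaLenRange", 15L),
    .checkProb(object@overlapProbability, "overlapProbability"),
    .checkProb(object@minus1BaseWeights, "minus1BaseWeights"),
    .checkProb(object@escapeProb, "escapeProb"),
    .checkProb(object@couplingAttenuation, "couplingAttenuation"),
    .checkProb(object@stallRetainProb, "stallRetainProb"),
    .checkProb(object@reverseStrandFraction, "reverseStrandFraction")
  )
  if (object@nOperons < 1L) msgs <- c(msgs, "'nOperons' must be >= 1")
  if (!identical(sort(names(object@minus1BaseWeights)), .BASES))
    msgs <- c(msgs, "'minus1BaseWeights' must be named A, C, G, T")
  else if (abs(sum(object@minus1BaseWeights) - 1) > 1e-8)
    msgs <- c(msgs, "'minus1BaseWeights' must sum to 1")
  if (!identical(sort(names(object@escapeProb)), .BASES))
    msgs <- c(msgs, "'escapeProb' must be named A, C, G, T")
  if (object@riboDepth < 0 || object@rnaDepth < 0)
    msgs <- c(msgs, "depths must be nonnegative")
  if (length(msgs)) msgs else TRUE
})

#' Construct a SimConfig
#'
#' Defaults encode the study conditions the simulator is meant to emulate:
#' roughly 300 leadered genes in ~100 operons, footprints of 25-40 nt,
#' RNA fragments of 25-45 nt, escape probabilities ordered G << C < U = A,
#' and halved arrest probability for start/stop-overlapping gene pairs.
#'
#' @param nOperons,genesPerOperon,cdsLengthCodons,utr5Length,overlapProbability
#'   genome architecture; see [SimConfig-class].
#' @param minus1BaseWeights,escapeProb,couplingAttenuation,stallRetainProb
#'   mechanistic model; see [SimConfig-class].
#' @param riboDepth,rnaDepth,riboLenRange,rnaLenRange sequencing emulation.
#' @param abundanceMeanlog,abundanceSdlog,reverseStrandFraction,repliconLength,seed
#'   see [SimConfig-class].
#' @return A validated [SimConfig-class] object.
#' @examples
#' cfg <- simConfig(nOperons = 10L, seed = 1L)
#' cfg
#' @export
simConfig <- function(nOperons = 100L,
                      genesPerOperon = c(1L, 5L),
                      cdsLengthCodons = c(60L, 300L),
                      utr5Length = c(20L, 60L),
                      overlapProbability = 0.3,
                      minus1BaseWeights = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                      escapeProb = c(A = 0.6, C = 0.3, G = 0.05, T = 0.6),
                      couplingAttenuation = 0.5,
                      stallRetainProb = 0.8,
                      riboDepth = 2e5,
                      rnaDepth = 2e5,
                      riboLenRange = c(25L, 40L),
                      rnaLenRange = c(25L, 45L),
                      abundanceMeanlog = 0,
                      abundanceSdlog = 1,
                      reverseStrandFraction = 0,
                      repliconLength = NA_integer_,
                      seed = 1L) {
  new("SimConfig",
      nOperons = as.integer(nOperons),
      genesPerOperon = as.integer(genesPerOperon),
      cdsLengthCodons = as.integer(cdsLengthCodons),
      utr5Length = as.integer(utr5Length),
      overlapProbability = overlapProbability,
      minus1BaseWeights = minus1BaseWeights[.BASES],
      escapeProb = escapeProb[.BASES],
      couplingAttenuation = couplingAttenuation,
      stallRetainProb = stallRetainProb,
      riboDepth = riboDepth,
      rnaDepth = rnaDepth,
      riboLenRange = as.integer(riboLenRange),
      rnaLenRange = as.integer(rnaLenRange),
      abundanceMeanlog = abundanceMeanlog,
      abundanceSdlog = abundanceSdlog,
      reverseStrandFraction = reverseStrandFraction,
      repliconLength = as.integer(repliconLength),
      seed = as.integer(seed))
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@nOperons, "operons,",
      paste(object@genesPerOperon, collapse = "-"), "genes/operon\n")
  cat("  escapeProb:",
      paste(sprintf("%s=%.3g", names(object@escapeProb), object@escapeProb),
            collapse = " "), "\n")
  cat("  couplingAttenuation:", object@couplingAttenuation,
      " stallRetainProb:", object@stallRetainProb, "\n")
  cat("  depth ribo/rna:", object@riboDepth, "/", object@rnaDepth,
      " seed:", object@seed, "\n")
})

#' Synthetic genome with annotation and generative truth
#'
#' @slot sequence [Biostrings::DNAStringSet] with one replicon.
#' @slot genes [GenomicRanges::GRanges] of CDS intervals (1-based, stop codon
#'   included) with metadata columns \code{gene_id}, \code{utr5_len},
#'   \code{operon_id}, \code{operon_rank}, \code{minus1_base},
#'   \code{category}, \code{leaderless}.
#' @slot truth per-gene generative truth: -1 base, coupling status, effective
#'   escape probability, transcript abundance.
#' @export
setClass("SimGenome", representation(
  sequence = "DNAStringSet",
  genes = "GRanges",
  truth = "data.frame"
))

setValidity("SimGenome", function(object) {
  g <- object@genes
  if (length(g) != nrow(object@truth)) return("genes and truth disagree in length")
  sl <- Biostrings::width(object@sequence)[1]
  if (any(GenomicRanges::start(g) < 1) || any(GenomicRanges::end(g) > sl))
    return("gene intervals exceed the replicon")
  if (any(GenomicRanges::width(g) %% 3L != 0L))
    return("CDS lengths must be divisible by 3")
  TRUE
})

#' @describeIn SimGenome-class replicon sequence(s).
#' @param x a \code{SimGenome}.
#' @export
genomeSequence <- function(x) x@sequence

#' @describeIn SimGenome-class gene annotation as a \code{GRanges}.
#' @export
geneModels <- function(x) x@genes

#' @describeIn SimGenome-class generative truth table.
#' @export
simTruth <- function(x) x@truth

setMethod("show", "SimGenome", function(object) {
  cat("SimGenome:", length(object@genes), "genes on",
      length(object@sequence), "replicon(s) of",
      sum(Biostrings::width(object@sequence)), "nt\n")
  cat("  categories:",
      paste(names(table(object@genes$category)),
            table(object@genes$category), sep = "=", collapse = " "), "\n")
})

#' Per-base, per-strand density track
#'
#' Holds either A-site-assigned ribosome density (each accepted footprint
#' contributes a unit mass at the first base of its A-site codon) or
#' fractional RNA-seq coverage (an N-nt fragment contributes 1/N at each
#' covered base). In both cases the total mass equals the number of accepted
#' reads.
#'
#' @slot kind \code{"ribo_Asite"} or \code{"rna_fractional"}.
#' @slot mass total mass = accepted read count.
#' @slot tracks named list (per replicon) of lists with \code{"+"} and
#'   \code{"-"} run-length encoded coverage vectors.
#' @slot seqlengths named integer vector of replicon lengths.
#' @export
setClass("DensityTrack", representation(
  kind = "character",
  mass = "numeric",
  tracks = "list",
  seqlengths = "integer"
))

setValidity("DensityTrack", function(object) {
  if (!object@kind %in% c("ribo_Asite", "rna_fractional"))
    return("kind must be 'ribo_Asite' or 'rna_fractional'")
  if (object@mass < 0) return("mass must be nonnegative")
  TRUE
})

#' @describeIn DensityTrack-class total mass (accepted read count).
#' @param x a \code{DensityTrack}.
#' @export
trackMass <- function(x) x@mass

#' @describeIn DensityTrack-class track kind.
#' @export
trackKind <- function(x) x@kind

#' @describeIn DensityTrack-class extract one strand of one replicon as a
#'   plain numeric vector (length = replicon length).
#' @param replicon replicon name (default: the first).
#' @param strand \code{"+"} or \code{"-"}.
#' @export
trackVector <- function(x, replicon = names(x@tracks)[1], strand = "+") {
  stopifnot(replicon %in% names(x@tracks), strand %in% c("+", "-"))
  as.numeric(x@tracks[[replicon]][[strand]])
}

setMethod("show", "DensityTrack", function(object) {
  cat("DensityTrack [", object@kind, "]: mass ", format(object@mass),
      " over ", length(object@tracks), " replicon(s)\n", sep = "")
})

#' Position-specific binomial enrichment result
#'
#' Signed enrichment scores per (position, base) of a foreground set of
#' start-codon context strings against a background universe, with the
#' Bonferroni significance threshold over all base-by-position tests.
#'
#' @slot score 4 x width matrix (rows A,C,G,T): positive values are
#'   -log10 of the upper binomial tail (overrepresentation), negative values
#'   are log10 of the lower tail (underrepresentation).
#' @slot threshold significance line, -log10(alpha / (4 * width)).
#' @slot fgN foreground size.
#' @slot bgFreqs 4 x width per-position background base frequencies.
#' @slot offsets integer positions relative to the first base of the start
#'   codon.
#' @slot alpha family-wise error rate used for the threshold.
#' @export
setClass("MotifResult", representation(
  score = "matrix",
  threshold = "numeric",
  fgN = "integer",
  bgFreqs = "matrix",
  offsets = "integer",
  alpha = "numeric"
))

#' @describeIn MotifResult-class signed score matrix.
#' @param x a \code{MotifResult}.
#' @export
motifScores <- function(x) x@score

#' @describeIn MotifResult-class Bonferroni significance threshold.
#' @export
motifThreshold <- function(x) x@threshold

setMethod("show", "MotifResult", function(object) {
  cat("MotifResult: fg n =", object@fgN, ", width", ncol(object@score),
      ", threshold", round(object@threshold, 3), "\n")
  hits <- which(object@score > object@threshold, arr.ind = TRUE)
  if (nrow(hits)) {
    cat("  significant overrepresentation:\n")
    for (i in seq_len(nrow(hits)))
      cat(sprintf("    %s at %+d (score %.2f)\n",
                  rownames(object@score)[hits[i, 1]],
                  object@offsets[hits[i, 2]],
                  object@score[hits[i, 1], hits[i, 2]]))
  } else cat("  no position above threshold\n")
})
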
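test_that("genome construction respects configured architecture", {
  cfg <- smallConfig(genesPerOperon = c(1L, 3L))
  gn <- buildGenome(cfg)
  genes <- geneModels(gn)
  expect_gte(length(genes), 10L)
  expect_lte(length(genes), 30L)

  seq <- genomeSequence(gn)[[1]]
  starts <- GenomicRanges::start(genes)
  ends <- GenomicRanges::end(genes)
  plus <- as.character(GenomicRanges::strand(genes)) == "+"
  for (i in seq_along(genes)) {
    cds <- Biostrings::subseq(seq, starts[i], ends[i])
    if (!plus[i]) cds <- Biostrings::reverseComplement(cds)
    expect_identical(as.character(Biostrings::subseq(cds, 1, 3)), "ATG")
    stop <- as.character(Biostrings::subseq(cds, length(cds) - 2, length(cds)))
    expect_true(stop %in% c("TAA", "TAG", "TGA"))
    expect_identical(GenomicRanges::width(genes)[i] %% 3L, 0L)
    # the -1 base was written into the sequence
    m1pos <- if (plus[i]) starts[i] - 1L else ends[i] + 1L
    m1 <- as.character(Biostrings::subseq(seq, m1pos, m1pos))
    if (!plus[i]) m1 <- chartr("ACGT", "TGCA", m1)
    expect_identical(m1, genes$minus1_base[i])
  }
})

test_that("overlapping genes share sequence with the upstream stop codon", {
  gn <- buildGenome(smallConfig(overlapProbability = 1, genesPerOperon = c(3L, 3L)))
  genes <- geneModels(gn)
  tr <- simTruth(gn)
  expect_true(any(tr$overlapping))
  for (i in which(tr$overlapping)) {
    up <- which(genes$operon_id == genes$operon_id[i] &
                  genes$operon_rank == genes$operon_rank[i] - 1L)
    s <- as.character(GenomicRanges::strand(genes))[i]
    startCodon <- if (s == "+")
      c(GenomicRanges::start(genes)[i], GenomicRanges::start(genes)[i] + 2L)
    else c(GenomicRanges::end(genes)[i] - 2L, GenomicRanges::end(genes)[i])
    stopCodon <- if (s == "+")
      c(GenomicRanges::end(genes)[up] - 2L, GenomicRanges::end(genes)[up])
    else c(GenomicRanges::start(genes)[up], GenomicRanges::start(genes)[up] + 2L)
    overlap <- min(startCodon[2], stopCodon[2]) - max(startCodon[1], stopCodon[1]) + 1L
    expect_gte(overlap, 1L)
  }
})

test_that("identical configurations reproduce byte-identical outputs", {
  cfg <- smallConfig()
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  writeSimulation(buildGenome(cfg), d1)
  writeSimulation(buildGenome(cfg), d2)
  for (f in c("genome.fa", "genes.gff3", "operons.tsv", "truth.tsv"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  r1 <- simulateRiboseq(buildGenome(cfg), "drug", cfg)
  r2 <- simulateRiboseq(buildGenome(cfg), "drug", cfg)
  expect_identical(r1, r2)
})

test_that("a degenerate -1 base distribution is honored exactly", {
  gn <- buildGenome(smallConfig(minus1BaseWeights = c(A = 0, C = 0, G = 1, T = 0)))
  expect_true(all(geneModels(gn)$minus1_base == "G"))
})

test_that("truth escape probability is a pure function of -1 base and coupling", {
  cfg <- smallConfig(overlapProbability = 0.5, genesPerOperon = c(2L, 4L))
  tr <- simTruth(buildGenome(cfg))
  expected <- ifelse(tr$overlapping,
                     1 - (1 - cfg@escapeProb[tr$minus1_base]) * cfg@couplingAttenuation,
                     cfg@escapeProb[tr$minus1_base])
  expect_equal(tr$escape_true, unname(expected))
})

test_that("infeasible packing is rejected with a clear message", {
  expect_error(buildGenome(smallConfig(repliconLength = 500L)),
               "infeasible packing")
})

test_that("with full escape the drug condition matches the control statistically", {
  cfg <- smallConfig(escapeProb = c(A = 1, C = 1, G = 1, T = 1),
                     riboDepth = 5e4, rnaDepth = 5e4)
  res <- runAll(cfg)
  expect_lt(abs(median(res$delta$log2_te_change)), 0.05)
})

test_that("with zero escape and full retention all drug footprints sit at the start codon", {
  cfg <- smallConfig(minus1BaseWeights = c(A = 0, C = 0, G = 1, T = 0),
                     escapeProb = c(A = 0, C = 0, G = 0, T = 0),
                     stallRetainProb = 1, overlapProbability = 0)
  gn <- buildGenome(cfg)
  reads <- simulateRiboseq(gn, "drug", cfg)
  genes <- geneModels(gn)
  plus <- reads$strand == "+"
  aSite <- ifelse(plus, reads$pos + reads$len - 1L - 12L, reads$pos + 12L)
  starts <- ifelse(as.character(GenomicRanges::strand(genes)) == "+",
                   GenomicRanges::start(genes), GenomicRanges::end(genes))
  expect_true(all(aSite %in% starts))
  # and the drug library equals the expected number of arrested-retained events
  expect_gt(nrow(reads), 0)
})

test_that("drug/control body density ratio recovers the escape probability", {
  # G(-1) everywhere, no coupling: expected body (post-head) ratio = 0.05
  cfg <- smallConfig(nOperons = 20L, minus1BaseWeights = c(A = 0, C = 0, G = 1, T = 0),
                     overlapProbability = 0, riboDepth = 2e5)
  gn <- buildGenome(cfg)
  sl <- setNames(Biostrings::width(genomeSequence(gn)), names(genomeSequence(gn)))
  ctl <- assignRiboDensity(simulateRiboseq(gn, "control", cfg), sl)
  drg <- assignRiboDensity(simulateRiboseq(gn, "drug", cfg), sl)
  genes <- geneModels(gn)
  bodySum <- function(track) {
    v <- vapply(seq_along(genes), function(i) {
      s <- as.character(GenomicRanges::strand(genes))[i]
      from <- if (s == "+") GenomicRanges::start(genes)[i] + 15L else GenomicRanges::start(genes)[i]
      to <- if (s == "+") GenomicRanges::end(genes)[i] else GenomicRanges::end(genes)[i] - 15L
      sum(trackVector(track, "chrSim", s)[from:to])
    }, numeric(1))
    sum(v)
  }
  ratio <- bodySum(drg) / bodySum(ctl)
  expect_equal(log2(ratio), log2(0.05), tolerance = 0.05)
})

test_that("RNA-seq simulation respects depth, abundance and transcript bounds", {
  cfg <- smallConfig(rnaDepth = 0)
  gn <- buildGenome(cfg)
  expect_identical(nrow(simulateRnaseq(gn, cfg)), 0L)
  p <- withr::local_tempfile(fileext = ".sam")
  writeSam(simulateRnaseq(gn, cfg), gn, p)
  expect_true(all(startsWith(readLines(p), "@")))  # header-only valid SAM

  # all mass on one transcript
  cfg2 <- smallConfig(nOperons = 5L, genesPerOperon = c(1L, 1L), rnaDepth = 2000)
  gn2 <- buildGenome(cfg2)
  gn2@truth$abundance <- c(1, rep(0, nrow(gn2@truth) - 1))
  reads <- simulateRnaseq(gn2, cfg2)
  g1 <- geneModels(gn2)[1]
  txFrom <- GenomicRanges::start(g1) - g1$utr5_len
  expect_true(all(reads$pos >= txFrom &
                    reads$pos + reads$len - 1L <= GenomicRanges::end(g1)))

  # 4:1 abundance ratio recovered within binomial error
  gn2@truth$abundance <- c(4, 1, rep(0, nrow(gn2@truth) - 2))
  cfg3 <- smallConfig(nOperons = 5L, genesPerOperon = c(1L, 1L), rnaDepth = 2e4)
  reads <- simulateRnaseq(gn2, cfg3)
  g2 <- geneModels(gn2)[2]
  n1 <- sum(reads$pos + reads$len - 1L <= GenomicRanges::end(g1))
  n2 <- sum(reads$pos >= GenomicRanges::start(g2) - g2$utr5_len)
  expect_equal(n1 / n2, 4, tolerance = 0.15)
})

test_that("unknown condition labels and empty genomes are rejected", {
  cfg <- smallConfig()
  gn <- buildGenome(cfg)
  expect_error(simulateRiboseq(gn, "treated", cfg))
})
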
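samFile <- function(records, seqlen = 2000L) {
  path <- tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               sprintf("@SQ\tSN:chr\tLN:%d", seqlen),
               records), path)
  path
}

samRecord <- function(qname, flag, pos, len, cigar = paste0(len, "M"),
                      tags = "NH:i:1") {
  paste(qname, flag, "chr", pos, 255, cigar, "*", 0, 0,
        strrep("A", len), "*", tags, sep = "\t")
}

test_that("alignment reading drops unmapped, multi-mapping, off-length and gapped records", {
  path <- samFile(c(
    samRecord("keep30", 0, 101, 30),
    samRecord("unmapped", 4, 0, 30),
    samRecord("multi", 0, 150, 30, tags = "NH:i:2"),
    samRecord("short", 0, 200, 15),
    samRecord("long", 0, 250, 50),
    samRecord("gapped", 0, 300, 30, cigar = "10M5N20M")))
  expect_warning(
    reads <- suppressMessages(readAlignments(path, lengthFilter = c(25, 45))),
    "gapped")
  expect_identical(reads$qname, "keep30")
  expect_error(suppressMessages(readAlignments(path, strict = TRUE)), "gapped")

  # without NH tags, duplicated query names mark multi-mappers
  path2 <- samFile(c(samRecord("a", 0, 101, 30, tags = "XX:i:1"),
                     samRecord("a", 0, 400, 30, tags = "XX:i:1"),
                     samRecord("b", 16, 140, 28, tags = "XX:i:1")))
  reads2 <- suppressMessages(readAlignments(path2, lengthFilter = c(25, 45)))
  expect_identical(reads2$qname, "b")
  expect_identical(reads2$strand, "-")
})

test_that("BED6 input is converted from 0-based half-open coordinates", {
  path <- tempfile(fileext = ".bed")
  writeLines("chr\t982\t1012\tr1\t0\t+", path)
  reads <- suppressMessages(readAlignments(path, lengthFilter = c(25, 45)))
  expect_identical(reads$pos, 983L)
  expect_identical(reads$len, 30L)
})

test_that("A-site assignment follows the 3'-end minus 12 nt rule on both strands", {
  # plus strand: 0-based left 982, length 30 -> unit mass at 0-based 999
  reads <- data.frame(qname = c("p", "m"), rname = "chr",
                      strand = c("+", "-"), pos = c(983L, 501L),
                      len = c(30L, 28L))
  track <- assignRiboDensity(reads, c(chr = 2000L))
  plus <- trackVector(track, "chr", "+")
  minus <- trackVector(track, "chr", "-")
  expect_identical(which(plus == 1), 1000L)   # 1-based for 0-based 999
  expect_identical(which(minus == 1), 513L)   # 1-based for 0-based 512
  expect_equal(trackMass(track), 2)

  # off-replicon A-site positions are dropped with a warning
  bad <- data.frame(qname = "x", rname = "chr", strand = "-",
                    pos = 1995L, len = 30L)
  expect_warning(t2 <- assignRiboDensity(bad, c(chr = 2000L)), "off-replicon")
  expect_equal(trackMass(t2), 0)
})

test_that("fractional RNA density gives each read total mass exactly 1", {
  reads <- data.frame(qname = c("a", "b", "c", "d"), rname = "chr",
                      strand = "+", pos = c(101L, 101L, 500L, 900L),
                      len = c(30L, 30L, 25L, 45L))
  track <- assignRnaDensity(reads, c(chr = 2000L))
  v <- trackVector(track, "chr", "+")
  expect_equal(v[101:130], rep(2 / 30, 30))
  expect_equal(sum(v[500:524]), 1, tolerance = 1e-12)
  expect_equal(sum(v), 4, tolerance = 1e-12)
  expect_equal(trackMass(track), 4)

  over <- data.frame(qname = "x", rname = "chr", strand = "+",
                     pos = 1990L, len = 30L)
  expect_error(assignRnaDensity(over, c(chr = 2000L)), "input error")
})

test_that("mass is conserved through a SAM round trip", {
  cfg <- smallConfig(riboDepth = 5e3, rnaDepth = 5e3)
  gn <- buildGenome(cfg)
  sl <- setNames(Biostrings::width(genomeSequence(gn)), names(genomeSequence(gn)))
  rp <- tempfile(fileext = ".sam"); np <- tempfile(fileext = ".sam")
  writeSam(simulateRiboseq(gn, "control", cfg), gn, rp)
  writeSam(simulateRnaseq(gn, cfg), gn, np)
  ribo <- suppressMessages(readAlignments(rp, c(20, 45)))
  rna <- suppressMessages(readAlignments(np, c(25, 45)))
  rt <- assignRiboDensity(ribo, sl)
  nt <- assignRnaDensity(rna, sl)
  expect_equal(trackMass(rt), nrow(ribo))
  expect_equal(trackMass(nt), nrow(rna))
  total <- sum(trackVector(nt, "chrSim", "+")) + sum(trackVector(nt, "chrSim", "-"))
  expect_equal(total, nrow(rna), tolerance = 1e-9)
})

test_that("RPKM and TE follow their closed forms and the expression floor", {
  genes <- makeGenes(1001L, 1500L, seqlen = 4000L)  # 500 nt CDS
  plus <- numeric(4000); plus[1001:1010] <- 1       # ribo_count = 10
  ribo <- vectorTrack(plus, mass = 1e6, replicon = "chr")
  rplus <- numeric(4000); rplus[1001:1500] <- 0.02  # rna_count = 10
  rna <- vectorTrack(rplus, mass = 1e6, kind = "rna_fractional", replicon = "chr")
  q <- quantifyGenes(ribo, rna, genes, riboCountFloor = 1)
  expect_equal(q$ribo_rpkm, 20)   # 10 / (0.5 kb * 1 M)
  expect_equal(q$rna_rpkm, 20)
  expect_equal(q$te, 1)

  # ribo_rpkm 20, rna_rpkm 10 -> te 2
  rna2 <- vectorTrack(rplus / 2, mass = 1e6, kind = "rna_fractional")
  q2 <- quantifyGenes(ribo, rna2, genes, riboCountFloor = 1)
  expect_equal(q2$te, 2)

  # below the RNA floor: te undefined, flagged not expressed
  q3 <- quantifyGenes(ribo, rna2, genes, rnaRpkmFloor = 50, riboCountFloor = 1)
  expect_true(is.na(q3$te))
  expect_false(q3$expressed)

  empty <- vectorTrack(numeric(4000), mass = 0, kind = "rna_fractional")
  expect_error(quantifyGenes(ribo, empty, genes), "empty library")
})

test_that("RPKM is invariant under joint rescaling and TE under library rescaling", {
  genes <- makeGenes(1001L, 1600L, seqlen = 4000L)
  plus <- numeric(4000); plus[seq(1001, 1600, 3)] <- 2
  ribo1 <- vectorTrack(plus, mass = 5000)
  ribo2 <- vectorTrack(plus * 7, mass = 5000 * 7)
  rplus <- numeric(4000); rplus[1001:1600] <- 0.05
  rna1 <- vectorTrack(rplus, mass = 3000, kind = "rna_fractional")
  rna2 <- vectorTrack(rplus * 3, mass = 3000 * 3, kind = "rna_fractional")
  q11 <- quantifyGenes(ribo1, rna1, genes, riboCountFloor = 1)
  q22 <- quantifyGenes(ribo2, rna2, genes, riboCountFloor = 1)
  expect_equal(q11$ribo_rpkm, q22$ribo_rpkm)
  expect_equal(q11$te, q22$te)
})

test_that("mirrored minus-strand genes quantify identically to plus-strand ones", {
  L <- 3000L
  genes <- makeGenes(1001L, 1300L, seqlen = L)
  reads <- data.frame(qname = sprintf("r%d", 1:50), rname = "chr", strand = "+",
                      pos = as.integer(seq(1005, 1250, length.out = 50)),
                      len = 30L)
  # mirror: position x -> L - x + 1
  mirrored <- data.frame(qname = reads$qname, rname = "chr", strand = "-",
                         pos = L - (reads$pos + reads$len - 1L) + 1L,
                         len = reads$len)
  genesM <- makeGenes(L - 1300L + 1L, L - 1001L + 1L, strand = "-", seqlen = L)
  rnaP <- data.frame(qname = "n", rname = "chr", strand = "+", pos = 1001L, len = 30L)
  rnaM <- data.frame(qname = "n", rname = "chr", strand = "-",
                     pos = L - 1030L + 1L, len = 30L)
  qP <- quantifyGenes(assignRiboDensity(reads, c(chr = L)),
                      assignRnaDensity(rnaP, c(chr = L)), genes, riboCountFloor = 1)
  qM <- quantifyGenes(assignRiboDensity(mirrored, c(chr = L)),
                      assignRnaDensity(rnaM, c(chr = L)), genesM, riboCountFloor = 1)
  expect_equal(qP$ribo_count, qM$ribo_count)
  expect_equal(qP$te, qM$te)
})

test_that("relative occupancy scales linearly with the global factor", {
  genes <- makeGenes(1001L, 1300L, seqlen = 3000L)
  plus <- numeric(3000); plus[1001:1300] <- 0.5
  track <- vectorTrack(plus)
  occ1 <- relativeOccupancy(track, genes[1], rnaRpkm = 2, globalFactor = 1)
  occHalf <- relativeOccupancy(track, genes[1], rnaRpkm = 2, globalFactor = 0.5)
  expect_equal(occHalf, occ1 * 0.5)
  expect_equal(unname(occ1[names(occ1) == "0"]), 0.25)  # d * s / r = 0.5/2
  expect_identical(names(occ1)[1], "-20")               # UTR included
  expect_error(relativeOccupancy(track, genes[1], rnaRpkm = 0), "rnaRpkm")
})
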
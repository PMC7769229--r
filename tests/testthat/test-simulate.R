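test_that("generateReference is seeded, GC-calibrated, and bounded", {
  a <- generateReference(10000, 0.5, seed = 7)
  b <- generateReference(10000, 0.5, seed = 7)
  expect_identical(segSeq(a), segSeq(b))
  gcFrac <- mean(strsplit(segSeq(a), "")[[1]] %in% c("G", "C"))
  expect_lt(abs(gcFrac - 0.5), 0.03)  # 99.9% binomial bound at n = 10000
  expect_error(generateReference(50), "short")
})

test_that("plantInversionSite installs the deletion motif at pb", {
  seg <- GenomeSegment("t", "TTTTGGGATGCCGGGG")
  out <- plantInversionSite(seg, 7, 12)
  expect_identical(segSeq(out$segment), "TTTTACAATGCCGGGG")
  ## planted site satisfies the construction precondition
  expect_silent(buildInvertedHaplotype(out$segment, out$spec))
  expect_error(plantInversionSite(seg, 2, 12), "range")
})

test_that("simulateCross draws Mendelian genotypes with phenotype rules", {
  off <- simulateCross("H1H1", "H1H2", 400, seed = 3)
  expect_true(all(off$genotype %in% c("H1H1", "H1H2")))
  off2 <- simulateCross("H1H1", "H1H1", 5, seed = 3)
  expect_identical(off2$genotype, rep("H1H1", 5))
  expect_identical(off2$phenotype, rep("round", 5))

  f2 <- simulateCross("H1H2", "H1H2", 2000, seed = 4)
  expect_identical(unname(f2$phenotype[f2$genotype == "H2H2"][1]), "aborted")
  expect_true(all(f2$phenotype[f2$genotype == "H1H2"] == "flat"))

  ## chi-square goodness of fit at n = 10,000 for each parent combination
  combos <- list(list("H1H1", "H1H2", c(1, 1), c("H1H1", "H1H2")),
                 list("H1H2", "H1H2", c(1, 2, 1),
                      c("H1H1", "H1H2", "H2H2")),
                 list("H1H2", "H2H2", c(1, 1), c("H1H2", "H2H2")))
  for (cb in combos) {
    off <- simulateCross(cb[[1]], cb[[2]], 10000, seed = 5)
    counts <- as.integer(table(factor(off$genotype, levels = cb[[4]])))
    expect_gt(segregationChisq(counts, cb[[3]])$p, 0.001)
  }
})

test_that("short-read pairs follow the count formula and truth labels", {
  loc <- smallLocus(seed = 51, length = 20000L, pb = 5000L, db = 15000L)
  ## H2 haplotype is one base shorter: 20 kb + (20 kb - 1)
  acc <- makeAccession(loc$pair, "H1H2", "acc")
  reads <- simulateShortReads(acc, coverage = 30, readLen = 150,
                              errRate = 0, seed = 9)
  expect_identical(nrow(reads) / 2, round(30 * 39999 / 600))

  ## error-free reads match their truth locus exactly
  haps <- c(A = segSeq(acc@hapA), B = segSeq(acc@hapB))
  idx <- sample(nrow(reads), 300)
  for (i in idx) {
    ref <- substr(haps[[reads$truth_hap[i]]], reads$truth_pos[i] + 1,
                  reads$truth_pos[i] + nchar(reads$seq[i]))
    expected <- if (reads$truth_strand[i] == "+") ref else naiveRevComp(ref)
    expect_identical(reads$seq[i], expected)
  }

  ## substitution rate lands within 3 binomial SDs of the target
  readsE <- simulateShortReads(acc, coverage = 10, readLen = 150,
                               errRate = 0.01, seed = 10)
  readsC <- simulateShortReads(acc, coverage = 10, readLen = 150,
                               errRate = 0, seed = 10)
  nBase <- sum(nchar(readsE$seq))
  mism <- sum(mapply(function(a, b)
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]]),
    readsE$seq, readsC$seq))
  expect_lt(abs(mism / nBase - 0.01), 3 * sqrt(0.01 * 0.99 / nBase))

  expect_error(simulateShortReads(acc, insertMean = 50000, seed = 1),
               "insert")
})

test_that("long reads carry the junction orientation-switch signal", {
  loc <- smallLocus(seed = 61, length = 6000L, pb = 1500L, db = 4500L)
  acc <- makeAccession(loc$pair, "H2H2", "h2")
  expect_identical(nrow(simulateLongReads(acc, coverage = 0, seed = 1)), 0L)

  reads <- simulateLongReads(acc, coverage = 20, lenMean = 1500,
                             lenSd = 200, errRate = 0, seed = 2)
  pb2 <- loc$pair@pb2; db2 <- loc$pair@db2
  ends <- reads$truth_pos + nchar(reads$seq)
  expect_true(any(reads$truth_pos < pb2 & ends > pb2))
  expect_true(any(reads$truth_pos < db2 & ends > db2))

  ## an error-free plus-strand read crossing pb2 switches orientation:
  ## prefix matches H1 forward, suffix matches H1 reverse-complemented
  h1 <- segSeq(wildHaplotype(loc$pair))
  i <- which(reads$truth_strand == "+" & reads$truth_pos < pb2 - 25 &
               ends > pb2 + 25)[1]
  expect_false(is.na(i))
  pre <- substr(reads$seq[i], 1, pb2 - reads$truth_pos[i])
  expect_identical(pre, substr(h1, reads$truth_pos[i] + 1, pb2))
  sufLen <- ends[i] - pb2
  suf <- substr(reads$seq[i], pb2 - reads$truth_pos[i] + 1,
                nchar(reads$seq[i]))
  expect_identical(suf, naiveRevComp(substr(h1, loc$db - sufLen + 1,
                                            loc$db)))
})

test_that("SNP panel dosages follow the group frequencies", {
  p0 <- simulateSnpPanel(5, 5, rep(0, 4), rep(0, 4), seed = 1)
  expect_true(all(p0$genotypes == 0))
  p1 <- simulateSnpPanel(5, 5, rep(1, 4), rep(0, 4), seed = 1)
  expect_true(all(p1$genotypes[p1$group == "flat", ] == 2))
  expect_true(all(p1$genotypes[p1$group == "round", ] == 0))
  ph <- simulateSnpPanel(200, 200, 0.5, 0.5, seed = 2)
  expect_lt(abs(mean(ph$genotypes) - 1), 3 * sqrt(2 * 0.25 / 400))
  expect_error(simulateSnpPanel(5, 5, c(0.5, 0.5), 0.5), "length")
})

test_that("expression counts scale with library size and plant the effect", {
  groups <- rep(c("FP", "RP"), each = 3)
  a <- simulateExpressionCounts(groups, 400, plantedLog2fc = 0,
                                dispersion = 0.05, libSize = 1e6, seed = 3)
  b <- simulateExpressionCounts(groups, 400, plantedLog2fc = 0,
                                dispersion = 0.05, libSize = 2e6, seed = 3)
  expect_lt(abs(sum(b$counts) / sum(a$counts) - 2), 0.05)
  expect_identical(dim(a$counts), c(400L, 6L))
  expect_true(all(a$geneLengths >= 500 & a$geneLengths <= 5000))
  expect_error(simulateExpressionCounts(c("FP", "FP", "RP"), 100), "two")

  ## planted log2 fold change is recovered within 0.5 log2 units on
  ## average (dispersion 0.05, n = 3 + 3, 20 replicates)
  est <- vapply(1:20, function(s) {
    sim <- simulateExpressionCounts(groups, 200, plantedLog2fc = 5,
                                    dispersion = 0.05, seed = 1000 + s)
    tpm <- tpmNormalize(sim$counts, sim$geneLengths)
    lfc <- log2FoldChange(tpm, sim$group)
    lfc[[sim$plantedGene]]
  }, numeric(1))
  expect_lt(abs(mean(est) - 5), 0.5)
})

test_that("simulators are bit-reproducible for a fixed seed", {
  loc <- smallLocus(seed = 71, length = 3000L, pb = 800L, db = 2500L)
  acc <- makeAccession(loc$pair, "H1H2", "a")
  expect_identical(simulateShortReads(acc, 5, seed = 5),
                   simulateShortReads(acc, 5, seed = 5))
  expect_identical(simulateLongReads(acc, 5, lenMean = 500, seed = 5),
                   simulateLongReads(acc, 5, lenMean = 500, seed = 5))
  expect_identical(simulateSnpPanel(4, 4, 0.4, 0.6, seed = 5),
                   simulateSnpPanel(4, 4, 0.4, 0.6, seed = 5))
  expect_identical(
    simulateExpressionCounts(rep(c("FP", "RP"), each = 2), 50, seed = 5),
    simulateExpressionCounts(rep(c("FP", "RP"), each = 2), 50, seed = 5))
  expect_identical(simulateCross("H1H2", "H1H2", 50, seed = 5),
                   simulateCross("H1H2", "H1H2", 50, seed = 5))
})

test_that("fruit shape classification follows the ratio thresholds", {
  expect_identical(classifyFruitShape(64, 40), "flat")        # r = 1.6
  expect_identical(classifyFruitShape(55, 50), "round")       # r = 1.1
  expect_identical(classifyFruitShape(13, 10), "unclassified")
  expect_identical(classifyFruitShape(c(64, 55), c(40, 50)),
                   c("flat", "round"))
  expect_error(classifyFruitShape(-1, 10), "positive")
})
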
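test_that("callGenotype applies the both-junctions-per-allele rule", {
  expect_identical(
    callGenotype(list(n_wpb = 10, n_wdb = 9, n_mpb = 0, n_mdb = 0))$genotype,
    "H1H1")
  expect_identical(
    callGenotype(list(n_wpb = 6, n_wdb = 5, n_mpb = 4, n_mdb = 7))$genotype,
    "H1H2")
  nc <- callGenotype(list(n_wpb = 1, n_wdb = 1, n_mpb = 1, n_mdb = 1))
  expect_identical(nc$genotype, "no_call")
  expect_match(nc$reason, "insufficient")
  ## one junction of an allele below threshold is not enough
  expect_identical(
    callGenotype(list(n_wpb = 10, n_wdb = 2, n_mpb = 5, n_mdb = 5))$genotype,
    "H2H2")
  expect_error(callGenotype(list(n_wpb = 1, n_wdb = 1, n_mpb = 1,
                                 n_mdb = 1), minReads = 0), "minReads")
})

test_that("insilicoPcr honours binding sites, orientation and haplotype", {
  pair <- toyPair()
  pp <- primerPair("P1", "TACA", "GGCA", minPrimerLen = 4)
  onH1 <- insilicoPcr(pp, wildHaplotype(pair))
  expect_true(onH1$present)
  expect_identical(onH1$ampliconLength, 9L)  # "TACAATGCC"
  ## the ACA deletion destroys the forward site on H2
  expect_false(insilicoPcr(pp, invertedHaplotype(pair))$present)
  ## swapping the fwd/rev labels leaves the chemistry unchanged (the
  ## template-orientation search makes the assay label-symmetric)
  swapped <- primerPair("x", "GGCA", "TACA", minPrimerLen = 4)
  expect_true(insilicoPcr(swapped, wildHaplotype(pair))$present)
  ## but a reverse primer written for the wrong strand (divergent pair)
  ## never amplifies
  divergent <- primerPair("y", "TACA", naiveRevComp("GGCA"),
                          minPrimerLen = 4)
  expect_false(insilicoPcr(divergent, wildHaplotype(pair))$present)
  expect_error(primerPair("short", "ACGT", "ACGTACGTACGTACG"), "length")
})

test_that("pcrGenotype maps band patterns to genotypes", {
  expect_identical(pcrGenotype("present", "absent", "absent")$genotype,
                   "H1H1")
  expect_identical(pcrGenotype("present", "present", "present")$genotype,
                   "H1H2")
  expect_identical(pcrGenotype("absent", "present", "present")$genotype,
                   "H2H2")
  odd <- pcrGenotype("present", "present", "absent")
  expect_identical(odd$genotype, "no_call")
  expect_match(odd$reason, "inconsistent")
})

test_that("designed diagnostic primers discriminate the two haplotypes", {
  loc <- smallLocus(seed = 111, length = 8000L, pb = 2000L, db = 6000L)
  primers <- designDiagnosticPrimers(loc$pair)
  h1 <- wildHaplotype(loc$pair); h2 <- invertedHaplotype(loc$pair)
  expect_true(insilicoPcr(primers$P1, h1)$present)
  expect_false(insilicoPcr(primers$P1, h2)$present)
  expect_false(insilicoPcr(primers$P2, h1)$present)
  expect_true(insilicoPcr(primers$P2, h2)$present)
  expect_false(insilicoPcr(primers$P3, h1)$present)
  expect_true(insilicoPcr(primers$P3, h2)$present)
  ## diploid band patterns give the three genotypes
  for (g in c("H1H1", "H1H2", "H2H2")) {
    acc <- makeAccession(loc$pair, g, g)
    expect_identical(pcrGenotypeAccession(acc, primers)$genotype, g)
  }
})

test_that("sequencing- and PCR-based calls agree on simulated accessions", {
  loc <- smallLocus(seed = 121, length = 8000L, pb = 2000L, db = 6000L)
  primers <- designDiagnosticPrimers(loc$pair)
  cross <- simulateCross("H1H2", "H1H2", 12, seed = 31)
  for (i in seq_len(nrow(cross))) {
    acc <- makeAccession(loc$pair, cross$genotype[i], cross$id[i])
    reads <- simulateShortReads(acc, coverage = 30, errRate = 0.005,
                                seed = 400 + i)
    seqCall <- genotypeFromReads(reads$seq, loc$junctions)
    pcrCall <- pcrGenotypeAccession(acc, primers)
    expect_identical(seqCall$genotype, cross$genotype[i])
    expect_identical(pcrCall$genotype, cross$genotype[i])
  }
})

test_that("no-call rate rises as coverage collapses", {
  loc <- smallLocus(seed = 131, length = 6000L, pb = 1500L, db = 4500L)
  rate <- function(coverage) {
    calls <- vapply(1:25, function(i) {
      acc <- makeAccession(loc$pair, "H1H2", "a")
      reads <- simulateShortReads(acc, coverage = coverage,
                                  errRate = 0.005, seed = 500 + i)
      genotypeFromReads(reads$seq, loc$junctions)$genotype
    }, character(1))
    mean(calls == "no_call")
  }
  expect_gt(rate(1), rate(30))
})

test_that("refineBreakpoints recovers the toy split coordinates", {
  ## toy read = H2[0:9): forward prefix ends at pb - 3 = 4, reverse-
  ## complemented suffix reaches the distal breakpoint at 12
  res <- refineBreakpoints("TTTTGGCAT", toyH1(), pbWindow = c(1, 8),
                           dbWindow = c(9, 14), minPart = 2)
  expect_identical(res$perRead$junction, "PB")
  expect_identical(res$consensus[["u"]], 4L)
  expect_identical(res$consensus[["v"]], 12L)
})

test_that("split alignment equals the exhaustive oracle on small loci", {
  set.seed(141)
  loc <- smallLocus(seed = 151, length = 400L, pb = 120L, db = 300L)
  h1 <- segSeq(wildHaplotype(loc$pair))
  h2 <- segSeq(invertedHaplotype(loc$pair))
  pbWin <- c(110, 130); dbWin <- c(290, 310)
  for (i in 1:12) {
    L <- sample(80:140, 1)
    start <- sample(c(max(1, 118 - L + 40), 60), 1)  # overlap pb2 = 117
    rd <- substr(h2, start, start + L - 1)
    if (i %% 2 == 0) rd <- naiveRevComp(rd)
    if (i %% 3 == 0) {
      p <- sample(nchar(rd), 1)
      substr(rd, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                         substr(rd, p, p)), 1)
    }
    got <- refineBreakpoints(rd, h1, pbWin, dbWin, minPart = 20)
    want <- bruteSplit(rd, h1, pbWin, dbWin, minPart = 20)
    if (is.null(want)) {
      expect_identical(nrow(got$perRead), 0L, info = paste("case", i))
    } else {
      expect_identical(nrow(got$perRead), 1L, info = paste("case", i))
      expect_identical(got$perRead$matches_fwd + got$perRead$matches_rev,
                       as.integer(want$total), info = paste("case", i))
    }
  }
})

test_that("reads without an orientation switch yield no estimate", {
  loc <- smallLocus(seed = 161, length = 6000L, pb = 1500L, db = 4500L)
  h1 <- segSeq(wildHaplotype(loc$pair))
  h2 <- segSeq(invertedHaplotype(loc$pair))
  inside <- substr(h2, 2000, 2999)   # wholly inside the inverted segment
  flank <- substr(h1, 100, 1099)     # wholly in shared upstream flank
  res <- refineBreakpoints(c(inside, flank), h1,
                           pbWindow = c(1450, 1550),
                           dbWindow = c(4450, 4550))
  expect_identical(nrow(res$perRead), 0L)
  expect_true(is.na(res$consensus[["u"]]))
})
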
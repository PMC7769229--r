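test_that("revComp complements, reverses, and is an involution", {
  expect_identical(revComp("ATGCC"), "GGCAT")
  expect_identical(revComp(""), "")
  expect_identical(revComp("ACGT"), "ACGT")  # palindrome fixed point
  expect_error(revComp("ACGN"), "alphabet")
  set.seed(11)
  for (i in 1:25) {
    s <- paste(sample(c("A", "C", "G", "T"), sample(1:80, 1), TRUE),
               collapse = "")
    expect_identical(revComp(revComp(s)), s)
    expect_identical(revComp(s), naiveRevComp(s))
    expect_identical(nchar(revComp(s)), nchar(s))
  }
})

test_that("buildInvertedHaplotype applies the inversion-with-indel rule", {
  pair <- toyPair()
  expect_identical(segSeq(invertedHaplotype(pair)), "TTTTGGCATGAGGGG")
  expect_identical(pair@pb2, 4L)
  expect_identical(pair@db2, 11L)
  expect_identical(segWidth(invertedHaplotype(pair)),
                   segWidth(wildHaplotype(pair)) - 1L)

  ## clean inversion of a palindromic segment is sequence-neutral
  h <- GenomeSegment("p", "AACCGGTT")
  p2 <- buildInvertedHaplotype(h, InversionSpec(2, 6, delMotif = "",
                                                insMotif = ""))
  expect_identical(segSeq(invertedHaplotype(p2)), "AACCGGTT")

  ## deleted-motif mismatch and inverted breakpoints are rejected
  expect_error(buildInvertedHaplotype(GenomeSegment("x", "TTTTTTTTTTTT"),
                                      InversionSpec(7, 10)),
               "precondition")
  expect_error(InversionSpec(9, 5), "pb")
})

test_that("H2 length bookkeeping holds for random specs and signatures", {
  set.seed(7)
  for (i in 1:60) {
    len <- sample(60:160, 1)
    dl <- sample(0:4, 1); il <- sample(0:4, 1)
    del <- paste(sample(c("A", "C", "G", "T"), dl, TRUE), collapse = "")
    ins <- paste(sample(c("A", "C", "G", "T"), il, TRUE), collapse = "")
    s <- paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = "")
    pb <- sample((dl + 1):(len - 2), 1)
    db <- sample((pb + 1):len, 1)
    if (dl > 0) substr(s, pb - dl + 1, pb) <- del
    pair <- buildInvertedHaplotype(GenomeSegment("r", s),
                                   InversionSpec(pb, db, del, ins))
    expect_identical(segWidth(invertedHaplotype(pair)) - len, il - dl)
  }
})

test_that("a clean inversion is recovered by inverting back", {
  set.seed(21)
  for (i in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T"), 120, TRUE), collapse = "")
    pb <- sample(5:50, 1); db <- sample((pb + 2):110, 1)
    spec <- InversionSpec(pb, db, delMotif = "", insMotif = "")
    fwd <- buildInvertedHaplotype(GenomeSegment("a", s), spec)
    back <- buildInvertedHaplotype(invertedHaplotype(fwd), spec)
    expect_identical(segSeq(invertedHaplotype(back)), s)
  }
})

test_that("buildJunctionSet extracts centred, clipped windows", {
  js <- toyJunctions(4L)
  expect_setequal(junctionIds(js), c("W_PB", "W_DB", "M_PB", "M_DB"))
  expect_identical(junction(js, "W_PB")@seq, "TACAATGC")
  expect_identical(junction(js, "W_DB")@seq, "TGCCGGGG")
  expect_identical(junction(js, "M_PB")@seq, "TTTTGGCA")
  expect_identical(junction(js, "M_DB")@seq, "ATGAGGGG")
  expect_true(all(vapply(js@junctions, function(j) j@center, integer(1)) ==
                    4L))

  ## flank larger than the sequence: window clips to the full haplotype
  big <- buildJunctionSet(toyPair(), 100L)
  expect_identical(junction(big, "W_PB")@seq, segSeq(toyH1()))
  expect_identical(junction(big, "W_PB")@center, 7L)

  expect_error(buildJunctionSet(toyPair(), 0), "flank")
})

test_that("proximal junctions carry the wild upstream flank", {
  set.seed(31)
  for (i in 1:10) {
    loc <- smallLocus(seed = 200 + i, length = 2000L, pb = 600L, db = 1500L)
    f <- sample(10:40, 1)
    js <- buildJunctionSet(loc$pair, f)
    h1 <- segSeq(wildHaplotype(loc$pair))
    w <- junction(js, "W_PB"); m <- junction(js, "M_PB")
    ## W_PB's upstream flank ends with the to-be-deleted motif at pb
    expect_identical(substr(w@seq, w@center - 2, w@center), "ACA")
    ## M_PB's upstream flank is wild H1 sequence ending at pb2 = pb - 3
    shared <- min(f, loc$pair@pb2)
    expect_identical(substr(m@seq, m@center - shared + 1, m@center),
                     substr(h1, loc$pair@pb2 - shared + 1, loc$pair@pb2))
    ## with an indel-free signature the two flanks coincide exactly
    spec0 <- InversionSpec(loc$pb, loc$db, delMotif = "", insMotif = "")
    p0 <- buildInvertedHaplotype(wildHaplotype(loc$pair), spec0)
    js0 <- buildJunctionSet(p0, f)
    expect_identical(
      substr(junction(js0, "W_PB")@seq, 1, junction(js0, "W_PB")@center),
      substr(junction(js0, "M_PB")@seq, 1, junction(js0, "M_PB")@center))
  }
})

test_that("motifScan matches the brute-force IUPAC matcher", {
  expect_identical(motifScan("AATGTCTCAA", "TGTCTC"),
                   data.frame(motif = "TGTCTC", pos = 2L, strand = "+"))
  hit <- motifScan("TTGAGACATT", "TGTCTC", bothStrands = TRUE)
  expect_identical(hit$strand, "-")
  expect_identical(nrow(motifScan("ACGT", "N")), 4L)
  expect_error(motifScan("ACGT", "TGX"), "IUPAC")

  set.seed(41)
  motifs <- c("TGTCTC", "RYN", "WWGW", "CANNTG")
  for (i in 1:30) {
    s <- paste(sample(c("A", "C", "G", "T"), sample(20:200, 1), TRUE),
               collapse = "")
    m <- sample(motifs, 1)
    both <- i %% 2 == 0
    expect_identical(motifScan(s, m, both), bruteMotifScan(s, m, both),
                     info = paste(m, s))
  }
})

test_that("CDS length maps to residue count with the stop codon removed", {
  expect_identical(cdsToProteinLength(1326), 441L)
  expect_identical(cdsToProteinLength(6), 1L)
  expect_error(cdsToProteinLength(1327), "CDS")
  expect_error(cdsToProteinLength(3), "CDS")
})
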
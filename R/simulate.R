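## Seeded simulators for every input the pipeline consumes. Each function
## calls set.seed(seed) when a seed is supplied, so a fixed (seed, parameter)
## pair is bit-reproducible.

.setSeed <- function(seed) if (!is.null(seed)) set.seed(as.integer(seed))

#' Generate a random reference segment
#'
#' I.i.d. bases with P(G) + P(C) = \code{gc}, split evenly within each pair.
#'
#' @param length integer(1) >= 100.
#' @param gc numeric(1) GC fraction in (0, 1).
#' @param seed integer(1) RNG seed (NULL to use the current RNG state).
#' @param id character(1) segment label.
#' @return A \linkS4class{GenomeSegment}.
#' @export
generateReference <- function(length, gc = 0.5, seed = NULL, id = "ref") {
  length <- as.integer(length)
  if (is.na(length) || length < 100L)
    stop("too short: reference 'length' must be >= 100")
  stopifnot(gc > 0, gc < 1)
  .setSeed(seed)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  GenomeSegment(id, paste(sample(names(p), length, replace = TRUE, prob = p),
                          collapse = ""))
}

#' Plant an invertible site into a reference segment
#'
#' Overwrites the bases immediately upstream of the proximal breakpoint with
#' the deletion motif, so that \code{\link{buildInvertedHaplotype}}'s
#' precondition holds by construction, and returns the matching
#' \linkS4class{InversionSpec}.
#'
#' @param segment a \linkS4class{GenomeSegment}.
#' @param pb,db breakpoints, 0-based half-open; the inverted interval is
#'   \code{[pb, db)}.
#' @param delMotif,insMotif the indel signature (defaults ACA / GA).
#' @return A list with elements \code{segment} (modified) and \code{spec}.
#' @export
plantInversionSite <- function(segment, pb, db, delMotif = "ACA",
                               insMotif = "GA") {
  stopifnot(is(segment, "GenomeSegment"))
  pb <- as.integer(pb); db <- as.integer(db)
  dlen <- nchar(delMotif)
  if (pb < dlen || pb >= db || db > segWidth(segment))
    stop("out-of-range breakpoints: need nchar(delMotif) <= pb < db <= length")
  s <- segment@seq
  if (dlen > 0L) substr(s, pb - dlen + 1L, pb) <- delMotif
  seg <- GenomeSegment(segment@id, s, segment@originOffset)
  list(segment = seg,
       spec = InversionSpec(pb, db, delMotif = delMotif,
                            insMotif = insMotif))
}

.alleles <- function(genotype) {
  if (!genotype %in% c("H1H1", "H1H2", "H2H2"))
    stop("parent genotype must be H1H1, H1H2 or H2H2")
  c(substr(genotype, 1L, 2L), substr(genotype, 3L, 4L))
}

#' Simulate an F1 cross at the inversion locus
#'
#' Each offspring receives one uniformly random allele from each parent;
#' phenotype follows deterministically from genotype (flat is fully dominant;
#' H2H2 homozygotes abort their fruit).
#'
#' @param parent1,parent2 parental genotypes (\code{"H1H1"}, \code{"H1H2"},
#'   \code{"H2H2"}).
#' @param n number of offspring.
#' @param seed RNG seed.
#' @param prefix id prefix for offspring.
#' @return A data.frame with columns \code{id}, \code{genotype},
#'   \code{phenotype}. Use \code{\link{makeAccession}} to attach haplotype
#'   sequences for read simulation.
#' @examples
#' table(simulateCross("H1H2", "H1H2", 40, seed = 1)$genotype)
#' @export
simulateCross <- function(parent1, parent2, n, seed = NULL, prefix = "F1") {
  n <- as.integer(n)
  stopifnot(n >= 0L)
  a1 <- .alleles(parent1); a2 <- .alleles(parent2)
  .setSeed(seed)
  g1 <- a1[sample.int(2L, n, replace = TRUE)]
  g2 <- a2[sample.int(2L, n, replace = TRUE)]
  geno <- ifelse(g1 <= g2, paste0(g1, g2), paste0(g2, g1))
  pheno <- vapply(geno, .phenotypeOf, character(1), USE.NAMES = FALSE)
  data.frame(id = sprintf("%s_%03d", prefix, seq_len(n) - 1L)[seq_len(n)],
             genotype = geno, phenotype = pheno)
}

## Vectorized strict reverse complement (one Biostrings call for the set).
.revCompVec <- function(seqs) {
  if (!length(seqs)) return(seqs)
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs)))
}

## Substitute bases i.i.d. at errRate; a hit base becomes one of the three
## other bases uniformly. Per-base independent flips are realized as a
## binomial error count per read plus uniformly placed distinct positions,
## which is distributionally identical and touches only reads with errors.
.injectErrors <- function(seqs, errRate) {
  if (errRate <= 0 || !length(seqs)) return(seqs)
  lens <- nchar(seqs)
  nerr <- rbinom(length(seqs), lens, errRate)
  bases <- c("A", "C", "G", "T")
  for (i in which(nerr > 0L)) {
    ch <- strsplit(seqs[i], "", fixed = TRUE)[[1L]]
    pos <- sample.int(lens[i], nerr[i])
    off <- sample.int(3L, nerr[i], replace = TRUE)
    ch[pos] <- bases[((match(ch[pos], bases) - 1L + off) %% 4L) + 1L]
    seqs[i] <- paste(ch, collapse = "")
  }
  seqs
}

.hapSeqs <- function(acc) {
  stopifnot(is(acc, "Accession"))
  c(A = segSeq(acc@hapA), B = segSeq(acc@hapB))
}

#' Simulate paired-end short reads from a diploid accession
#'
#' Fragments are drawn uniformly from a uniformly chosen haplotype; mate 1
#' reads the fragment's 5' end on the fragment strand and mate 2 reads the
#' 3' end reverse-complemented. Substitution errors are i.i.d.; qualities are
#' constant Phred 30 (downstream classification ignores quality). The number
#' of pairs is \code{round(coverage * (lenA + lenB) / (4 * readLen))}.
#'
#' @param acc an \linkS4class{Accession}.
#' @param coverage target diploid depth.
#' @param readLen read length, >= 30.
#' @param insertMean,insertSd fragment-size distribution; \code{insertMean}
#'   must be >= 2 * readLen.
#' @param errRate per-base substitution rate in [0, 0.1).
#' @param seed RNG seed.
#' @return A data.frame with one row per read: \code{id}, \code{mate} (1/2),
#'   \code{seq}, \code{qual}, \code{truth_hap} (A/B), \code{truth_pos}
#'   (0-based leftmost position on the source haplotype), and
#'   \code{truth_strand} (read orientation relative to the haplotype).
#' @export
simulateShortReads <- function(acc, coverage = 30, readLen = 150L,
                               insertMean = 450L, insertSd = 50,
                               errRate = 0.005, seed = NULL) {
  readLen <- as.integer(readLen)
  stopifnot(readLen >= 30L, insertMean >= 2L * readLen,
            errRate >= 0, errRate < 0.1)
  haps <- .hapSeqs(acc)
  hapLens <- nchar(haps)
  if (insertMean > min(hapLens))
    stop("insert longer than haplotype")
  .setSeed(seed)
  nPairs <- round(coverage * sum(hapLens) / (4 * readLen))
  if (nPairs < 1L) {
    return(data.frame(id = character(), mate = integer(), seq = character(),
                      qual = character(), truth_hap = character(),
                      truth_pos = integer(), truth_strand = character()))
  }
  hap <- sample(c("A", "B"), nPairs, replace = TRUE)
  hlen <- hapLens[hap]
  ins <- pmin(pmax(round(rnorm(nPairs, insertMean, insertSd)),
                   2L * readLen), hlen)
  start <- floor(runif(nPairs) * (hlen - ins + 1))      # 0-based fragment start
  fragStrand <- sample(c("+", "-"), nPairs, replace = TRUE)
  leftSeq <- substring(haps[hap], start + 1L, start + readLen)
  rightStart <- start + ins - readLen
  rightSeqF <- substring(haps[hap], rightStart + 1L, rightStart + readLen)
  rightSeqR <- .revCompVec(rightSeqF)
  plus <- fragStrand == "+"
  mate1seq <- ifelse(plus, leftSeq, rightSeqR)
  mate2seq <- ifelse(plus, rightSeqR, leftSeq)
  ## truth: leftmost haplotype position and orientation of each mate's seq
  mate1pos <- ifelse(plus, start, rightStart)
  mate2pos <- ifelse(plus, rightStart, start)
  mate1strand <- ifelse(plus, "+", "-")
  mate2strand <- ifelse(plus, "-", "+")
  ids <- sprintf("%s_r%05d", acc@id, seq_len(nPairs) - 1L)
  qual <- strrep("?", readLen)
  out <- data.frame(
    id = rep(ids, each = 2L),
    mate = rep(c(1L, 2L), nPairs),
    seq = as.vector(rbind(mate1seq, mate2seq)),
    qual = qual,
    truth_hap = rep(hap, each = 2L),
    truth_pos = as.integer(as.vector(rbind(mate1pos, mate2pos))),
    truth_strand = as.vector(rbind(mate1strand, mate2strand)))
  out$seq <- .injectErrors(out$seq, errRate)
  rownames(out) <- NULL
  out
}

#' Simulate single-end long reads from a diploid accession
#'
#' Read lengths follow a normal distribution truncated (by clamping) to
#' \code{[200, haplotype length]}. Reads from an H2 haplotype that cross a
#' junction carry the orientation-switch signal consumed by
#' \code{\link{refineBreakpoints}}.
#'
#' @param acc an \linkS4class{Accession}.
#' @param coverage target diploid depth; 0 yields an empty set.
#' @param lenMean,lenSd read-length distribution; \code{lenMean} >= 200.
#' @param errRate per-base substitution rate.
#' @param seed RNG seed.
#' @return A data.frame as in \code{\link{simulateShortReads}} with
#'   \code{mate = "none"}.
#' @export
simulateLongReads <- function(acc, coverage = 20, lenMean = 3000L,
                              lenSd = 500, errRate = 0, seed = NULL) {
  stopifnot(lenMean >= 200L, errRate >= 0, errRate < 0.1)
  haps <- .hapSeqs(acc)
  hapLens <- nchar(haps)
  .setSeed(seed)
  n <- round(coverage * sum(hapLens) / (2 * lenMean))
  if (n < 1L) {
    return(data.frame(id = character(), mate = character(), seq = character(),
                      qual = character(), truth_hap = character(),
                      truth_pos = integer(), truth_strand = character()))
  }
  hap <- sample(c("A", "B"), n, replace = TRUE)
  hlen <- hapLens[hap]
  len <- pmin(pmax(round(rnorm(n, lenMean, lenSd)), 200L), hlen)
  start <- floor(runif(n) * (hlen - len + 1))
  strand <- sample(c("+", "-"), n, replace = TRUE)
  seqF <- substring(haps[hap], start + 1L, start + len)
  seqs <- seqF
  minus <- strand == "-"
  if (any(minus)) seqs[minus] <- .revCompVec(seqF[minus])
  out <- data.frame(
    id = sprintf("%s_L%05d", acc@id, seq_len(n) - 1L),
    mate = "none",
    seq = .injectErrors(seqs, errRate),
    qual = vapply(len, function(l) strrep("?", l), character(1)),
    truth_hap = hap,
    truth_pos = as.integer(start),
    truth_strand = strand)
  rownames(out) <- NULL
  out
}

#' Simulate a biallelic SNP panel with group-specific allele frequencies
#'
#' Alt-allele dosages are drawn binomial(2, group frequency) per accession
#' per SNP, mimicking a panel of heterozygous SNPs screened for
#' flat-vs-round allele-frequency differences.
#'
#' @param nFlat,nRound accessions per phenotype group.
#' @param altFreqFlat,altFreqRound per-SNP alternative-allele frequencies
#'   (equal length, values in [0, 1]).
#' @param seed RNG seed.
#' @param positions optional integer positions (defaults to a seeded draw
#'   from a 225-kb window).
#' @return A list with \code{positions}, \code{genotypes} (accessions x SNPs
#'   dosage matrix, values 0/1/2), and \code{group} (per-accession
#'   \code{"flat"}/\code{"round"}).
#' @export
simulateSnpPanel <- function(nFlat, nRound, altFreqFlat, altFreqRound,
                             seed = NULL, positions = NULL) {
  if (length(altFreqFlat) != length(altFreqRound))
    stop("frequency vectors must have equal length")
  stopifnot(all(altFreqFlat >= 0 & altFreqFlat <= 1),
            all(altFreqRound >= 0 & altFreqRound <= 1),
            nFlat >= 1, nRound >= 1)
  m <- length(altFreqFlat)
  .setSeed(seed)
  if (is.null(positions))
    positions <- sort(sample.int(225000L, m))
  flat <- matrix(rbinom(nFlat * m, 2L, rep(altFreqFlat, each = nFlat)),
                 nrow = nFlat)
  round_ <- matrix(rbinom(nRound * m, 2L, rep(altFreqRound, each = nRound)),
                   nrow = nRound)
  geno <- rbind(flat, round_)
  rownames(geno) <- c(sprintf("flat_%03d", seq_len(nFlat)),
                      sprintf("round_%03d", seq_len(nRound)))
  colnames(geno) <- sprintf("snp_%d", positions)
  list(positions = as.integer(positions), genotypes = geno,
       group = c(rep("flat", nFlat), rep("round", nRound)))
}

#' Simulate an RNA-seq count matrix with one planted activated gene
#'
#' Counts are negative-binomial with log-normal gene base means, a common
#' dispersion, and library-size scaling. Exactly one gene's FP-group mean is
#' \code{2^plantedLog2fc} times its RP-group mean; all other genes have equal
#' group means. Gene lengths are uniform on [500, 5000] bp.
#'
#' @param groups per-sample labels, \code{"FP"} (flat) / \code{"RP"} (round),
#'   at least two samples per group.
#' @param nGenes number of genes.
#' @param plantedLog2fc log2 fold change (FP over RP) of the planted gene.
#' @param dispersion common NB dispersion (> 0); variance is
#'   \code{mu + dispersion * mu^2}.
#' @param libSize expected library size per sample.
#' @param seed RNG seed.
#' @return A list with \code{counts} (genes x samples), \code{geneLengths},
#'   \code{group}, \code{plantedGene} (gene id) and \code{plantedLog2fc}.
#' @export
simulateExpressionCounts <- function(groups, nGenes = 500L,
                                     plantedLog2fc = 5, dispersion = 0.05,
                                     libSize = 1e6, seed = NULL) {
  groups <- as.character(groups)
  if (!all(groups %in% c("FP", "RP")))
    stop("'groups' must contain only FP and RP")
  if (sum(groups == "FP") < 2L || sum(groups == "RP") < 2L)
    stop("need at least two samples per group")
  stopifnot(dispersion > 0, nGenes >= 2L)
  .setSeed(seed)
  base <- rlnorm(nGenes, meanlog = log(100), sdlog = 1)
  planted <- sample.int(nGenes, 1L)
  geneIds <- sprintf("gene_%04d", seq_len(nGenes))
  muFP <- muRP <- base
  muFP[planted] <- base[planted] * 2^plantedLog2fc
  nS <- length(groups)
  counts <- matrix(0L, nrow = nGenes, ncol = nS,
                   dimnames = list(geneIds, sprintf("%s%d", groups,
                     stats::ave(seq_len(nS), groups, FUN = seq_along))))
  for (s in seq_len(nS)) {
    mu <- if (groups[s] == "FP") muFP else muRP
    mu <- mu * (libSize / sum(mu))
    counts[, s] <- rnbinom(nGenes, mu = mu, size = 1 / dispersion)
  }
  list(counts = counts,
       geneLengths = as.integer(round(runif(nGenes, 500, 5000))),
       group = groups, plantedGene = geneIds[planted],
       plantedLog2fc = plantedLog2fc)
}

#' Classify fruit shape from cheek and vertical lengths
#'
#' Flat fruits have a cheek/vertical ratio above 1.5; round fruits below
#' 1.2; ratios in between are unclassified.
#'
#' @param cheekLen,verticalLen lengths in mm, both > 0 (vectorized).
#' @return character vector: \code{"flat"}, \code{"round"} or
#'   \code{"unclassified"}.
#' @examples
#' classifyFruitShape(64, 40)  # flat
#' @export
classifyFruitShape <- function(cheekLen, verticalLen) {
  if (any(cheekLen <= 0) || any(verticalLen <= 0))
    stop("lengths must be positive")
  r <- cheekLen / verticalLen
  ifelse(r > 1.5, "flat", ifelse(r < 1.2, "round", "unclassified"))
}
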
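#' Default demonstration configuration
#'
#' One flat list of every tunable the pipeline uses. The demo locus is a
#' 30-kb segment carrying a 20-kb inversion — a desk-scale stand-in for the
#' megabase-scale inversion the design targets — with the canonical ACA/GA
#' breakpoint indel signature. Defaults elsewhere: 30x short-read coverage of
#' 150-bp pairs at 0.5% substitution error, seed-and-extend k = 15 with
#' 15-bp minimum junction overhang and 0.9 identity, 3 spanning reads per
#' junction to accept an allele, and the |log2FC| > 2 / FDR < 0.1 expression
#' filter.
#'
#' @param seed integer master seed; all stage seeds derive from it.
#' @return A named list of parameters accepted by \code{\link{runDemo}}.
#' @export
demoConfig <- function(seed = 1L) {
  list(seed = as.integer(seed),
       ## locus
       locusLength = 30000L, pb = 5000L, db = 25000L,
       delMotif = "ACA", insMotif = "GA", gc = 0.4, flank = 300L,
       ## short reads
       coverage = 30, readLen = 150L, insertMean = 450L, insertSd = 50,
       errRate = 0.005,
       ## long reads
       longCoverage = 15, longLenMean = 3000L, longLenSd = 500,
       longErrRate = 0.01, refineWindow = 50L, minPart = 20L,
       ## classification / genotyping
       k = 15L, minOverhang = 15L, minIdentity = 0.9, minReads = 3L,
       ## cross
       parent1 = "H1H2", parent2 = "H1H2", nOffspring = 24L,
       ## SNP panel
       nFlat = 30L, nRound = 30L, nSnps = 63L,
       plantedSnpFreqFlat = 0.9, plantedSnpFreqRound = 0.1,
       nullSnpFreq = 0.5,
       ## expression
       nGenes = 300L, plantedLog2fc = 5, dispersion = 0.05, libSize = 1e6,
       nSamplesPerGroup = 3L, lfcThreshold = 2, fdrThreshold = 0.1,
       pseudocount = 1)
}

.stageSeed <- function(config, stage, i = 0L) {
  (config$seed * 1009L + stage * 131L + i) %% 2147483587L
}

#' Run the end-to-end demonstration pipeline
#'
#' Simulates the inversion locus, an F1 cross of two heterozygotes,
#' short-read and PCR genotyping of every offspring, breakpoint refinement
#' from H2 long reads, a SNP association panel and an expression screen,
#' writing every artefact (FASTA, FASTQ, TSVs) plus a run manifest of
#' parameter values and output checksums to \code{outDir}. The run is fully
#' determined by \code{config$seed}. The function stops if a pipeline-level
#' invariant fails (read/PCR genotype discordance, or imperfect
#' genotype-phenotype co-segregation).
#'
#' @param config list from \code{\link{demoConfig}}.
#' @param outDir output directory (created if needed).
#' @return Invisibly, a list with the manifest data.frame and the main
#'   stage results (\code{genotypes}, \code{segregation}, \code{breakpoints},
#'   \code{snp}, \code{deg}).
#' @export
runDemo <- function(config = demoConfig(), outDir = tempfile("flatpeach_")) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(outDir, f)

  ## stage 1: locus
  ref <- generateReference(config$locusLength, config$gc,
                           seed = .stageSeed(config, 1L), id = "locus")
  planted <- plantInversionSite(ref, config$pb, config$db,
                                config$delMotif, config$insMotif)
  pair <- buildInvertedHaplotype(planted$segment, planted$spec)
  junctions <- buildJunctionSet(pair, config$flank)
  writeFasta(list(pair@h1, pair@h2), out("haplotypes.fasta"))
  writeFasta(junctions, out("junctions.fasta"))

  ## stage 2: F1 cross, read-based + PCR genotyping, co-segregation
  cross <- simulateCross(config$parent1, config$parent2, config$nOffspring,
                         seed = .stageSeed(config, 2L))
  primers <- designDiagnosticPrimers(pair)
  calls <- do.call(rbind, lapply(seq_len(nrow(cross)), function(i) {
    acc <- makeAccession(pair, cross$genotype[i], cross$id[i])
    reads <- simulateShortReads(acc, config$coverage, config$readLen,
                                config$insertMean, config$insertSd,
                                config$errRate,
                                seed = .stageSeed(config, 2L, i))
    seqCall <- genotypeFromReads(reads$seq, junctions, config$minReads,
                                 config$k, maxMismatchFrac = 0.1,
                                 config$minOverhang, config$minIdentity)
    pcrCall <- pcrGenotypeAccession(acc, primers)
    cbind(id = acc@id, truth = acc@genotype, phenotype = acc@phenotype,
          seqCall, pcr_genotype = pcrCall$genotype,
          p1 = pcrCall$p1, p2 = pcrCall$p2, p3 = pcrCall$p3)
  }))
  writeTsv(calls, out("genotypes.tsv"))
  coseg <- cosegregationCheck(
    data.frame(id = calls$id, genotype = calls$genotype),
    data.frame(id = calls$id, phenotype = calls$phenotype))
  concordant <- all(calls$genotype == calls$pcr_genotype)
  if (!concordant)
    stop("stage genotyping: sequencing- and PCR-based calls disagree")
  if (!coseg$perfect)
    stop("stage cosegregation: genotype-phenotype co-segregation violated")
  counts <- c(H1H1 = sum(cross$genotype == "H1H1"),
              H1H2 = sum(cross$genotype == "H1H2"),
              H2H2 = sum(cross$genotype == "H2H2"))
  seg <- segregationChisq(counts, c(1, 2, 1))
  writeTsv(data.frame(genotype = names(counts), observed = counts,
                      expected = seg$expected, chi2 = seg$chi2, df = seg$df,
                      p = seg$p),
           out("segregation.tsv"))

  ## stage 3: breakpoint refinement from H2H2 long reads
  h2acc <- makeAccession(pair, "H2H2", "h2h2_ref")
  longReads <- simulateLongReads(h2acc, config$longCoverage,
                                 config$longLenMean, config$longLenSd,
                                 config$longErrRate,
                                 seed = .stageSeed(config, 3L))
  writeFastq(longReads, out("long_reads.fastq"))
  w <- config$refineWindow
  refined <- refineBreakpoints(longReads, pair@h1,
                               pbWindow = c(config$pb - w, config$pb + w),
                               dbWindow = c(config$db - w, config$db + w),
                               minPart = config$minPart)
  writeTsv(refined$perRead, out("breakpoints_per_read.tsv"))
  writeTsv(data.frame(coord = c("u", "v"), estimate = refined$consensus),
           out("breakpoints_consensus.tsv"))

  ## stage 4: SNP association
  freqFlat <- c(config$plantedSnpFreqFlat,
                rep(config$nullSnpFreq, config$nSnps - 1L))
  freqRound <- c(config$plantedSnpFreqRound,
                 rep(config$nullSnpFreq, config$nSnps - 1L))
  panel <- simulateSnpPanel(config$nFlat, config$nRound, freqFlat,
                            freqRound, seed = .stageSeed(config, 4L))
  snp <- snpAssociation(panel)
  writeTsv(snp, out("snp_association.tsv"))

  ## stage 5: expression screen
  groups <- rep(c("FP", "RP"), each = config$nSamplesPerGroup)
  sim <- simulateExpressionCounts(groups, config$nGenes,
                                  config$plantedLog2fc, config$dispersion,
                                  config$libSize,
                                  seed = .stageSeed(config, 5L))
  tpm <- tpmNormalize(sim$counts, sim$geneLengths)
  writeTsv(cbind(gene_id = rownames(tpm), as.data.frame(tpm)),
           out("tpm.tsv"))
  deg <- degScreen(sim$counts, sim$geneLengths, groups,
                   config$lfcThreshold, config$fdrThreshold,
                   config$pseudocount)
  writeTsv(deg, out("deg.tsv"))

  ## manifest: config echo + output checksums
  files <- sort(list.files(outDir, full.names = FALSE))
  files <- setdiff(files, "manifest.tsv")
  sums <- tools::md5sum(file.path(outDir, files))
  manifest <- rbind(
    data.frame(key = paste0("config.", names(config)),
               value = vapply(config, function(v) as.character(v)[1L],
                              character(1))),
    data.frame(key = paste0("md5.", files), value = unname(sums)))
  writeTsv(manifest, out("manifest.tsv"))

  invisible(list(manifest = manifest, genotypes = calls, segregation = seg,
                 breakpoints = refined, snp = snp, deg = deg,
                 cosegregation = coseg, outDir = outDir))
}
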
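---
title: "Methods: inversion breakpoint genotyping and the flat-fruit locus screen"
author: "flatpeach"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: inversion breakpoint genotyping and the flat-fruit locus screen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flatpeach)
```

# The biological problem

Flat fruit shape in peach is controlled by a single dominant locus on
chromosome 6. A megabase-scale chromosomal inversion at that locus
co-segregates with the trait: flat-fruited trees are heterozygous for the
inverted arrangement (H1H2), round-fruited trees are homozygous wild type
(H1H1), and inversion homozygotes (H2H2) abort their fruit early in
development, so the H2H2 class is absent among cultivated material. The
mutant haplotype carries a characteristic indel signature at its
breakpoints: three bases (ACA) deleted at the proximal breakpoint and two
bases (GA) inserted at the distal one, so H2 is exactly one base shorter
than H1. The inversion places a normally quiescent OVATE-family gene next
to new upstream sequence and activates it in developing flat fruit.

`flatpeach` packages the analyses this kind of study runs — haplotype and
junction construction, read-based and PCR-based diploid genotyping,
breakpoint refinement from split long reads, segregation and SNP
association statistics, and a TPM-based expression screen — as tested,
seedable functions, together with simulators that generate inputs with the
statistical structure the downstream methods assume.

# The haplotype model

An inversion is specified by 0-based half-open breakpoints: the inverted
segment is `H1[pb, db)`. The mutant haplotype is constructed as

```
H2 = H1[0, pb - |del|) + revcomp(H1[pb, db)) + ins + H1[db, end)
```

with `del = "ACA"`, `ins = "GA"` by default. Coordinate convention and the
placement of the indels are design choices: the deletion is modelled as the
`|del|` bases immediately upstream of `pb`, and the insertion sits between
the inverted segment and the downstream flank. Published breakpoint figures
show the indels at the junctions without base-exact placement; this
placement is symmetric, easy to state, and every downstream coordinate
(junction centres `pb2 = pb - |del|`, `db2 = pb2 + (db - pb) + |ins|`)
follows mechanically from it. A consequence worth knowing: proximal-junction
evidence can never observe `pb` itself — wild sequence on H2 ends at
`pb - 3` — so breakpoint estimates report `pb - 3`, not `pb`.

Four junction references are cut from the pair: the wild proximal and
distal breakpoints on H1 (`W_PB`, `W_DB`) and the two novel junctions on H2
(`M_PB`, `M_DB`), each a `2 * flank` window centred on the breakpoint.
Windows are clipped (not padded) at sequence ends, with the centre index
shifted accordingly; padding would fabricate sequence that alignment could
then match.

```{r toy}
h1 <- GenomeSegment("toy", "TTTTACAATGCCGGGG")
pair <- buildInvertedHaplotype(h1, InversionSpec(pb = 7, db = 12))
segSeq(invertedHaplotype(pair))
buildJunctionSet(pair, flank = 4)
```

# Read classification and genotyping

Reads are aligned to the four junctions with an ungapped seed-and-extend
aligner (compiled code): exact k-mer seeds locate diagonals, and each
diagonal is extended to the match-maximal span whose cumulative mismatch
fraction stays below a ceiling. Ungapped alignment is a deliberate
restriction — the inversion signature is substitution-free at junction
scale and the bundled simulator emits substitution errors only — and is a
documented limitation for real indel-bearing reads.

A read supports a junction when its alignment covers
`[center - minOverhang, center + minOverhang)` at or above a minimum
identity. Among spanning hits the unique maximal-matches junction wins;
ties across junctions are discarded as uninformative. This tie rule is
conservative on purpose: the wild and mutant junctions share one flank, so
a read confined to shared sequence must support neither haplotype.

Defaults: `k = 15`, `minOverhang = 15`, `minIdentity = 0.9`,
`maxMismatchFrac = 0.1`. None of these is dictated by the study design;
they are chosen so that a 150-bp read at sub-percent error either spans a
junction decisively or is discarded quickly. Mate information is unused:
the genotyping rule is read-level, and pairs are classified independently.

The diploid call requires both junctions of an allele:
H1 is present iff `W_PB` and `W_DB` each have at least `minReads` (default
3) spanning reads, H2 likewise for `M_PB`/`M_DB`; both alleles give H1H2,
neither gives a no-call. Presence/absence of the full junction pair — not
allelic balance — is exactly the published decision rule; a read-ratio
balance test would be a possible extension, not implemented here.

In-silico PCR mirrors the bench assay: pair P1 spans the wild proximal
breakpoint (H1-diagnostic), P2 and P3 span the two mutant junctions
(H2-diagnostic, must co-occur). A primer binds with at most
`maxMismatches` mismatches (default 0) and an exact 3'-terminal
trinucleotide; products report the shortest valid amplicon searching both
template orientations. Band patterns map to genotypes; any other pattern is
an inconsistent no-call.

# Breakpoint refinement from split long reads

A long read crossing a mutant junction switches orientation on H1: one part
aligns forward, the other aligns to the reverse complement. For each read
(and its reverse complement) the refiner exhaustively maximizes, over the
split index and all reference placements whose junction-side boundaries lie
inside user-supplied search windows, the total matches of the two parts —
one forward, one reverse-complement, in both junction orientations. Each
part must reach `minPart` (default 20) matches at a bounded mismatch
fraction; reads without a genuine orientation switch (for example reads
wholly inside the inverted segment) fail this and return no estimate. A
16-mer screen against the window neighbourhoods skips the exhaustive
alignment for reads that cannot qualify.

Alignment alone cannot identify a breakpoint to the base. Two effects
conspire: one-base microhomology at a junction produces equal-scoring
parses one base apart (roughly a coin flip per junction side on a random
reference), and the inserted motif at the distal junction can partially
match the reference just inside the window, letting a shifted parse
strictly outscore the true one. The refiner therefore exploits the known
indel signature, which is part of the locus configuration: a distal split
may consume the insertion motif from the read (its bases count as
explained rather than as forced mismatches), and exact score ties prefer
the parse that places the deletion motif at its expected H1 position.
With the signature in play, proximal-junction reads observe
`(u, v) = (pb - 3, db)` and distal-junction reads `(pb, db)` exactly on
error-free data. The consensus (per-coordinate majority) prefers
proximal-read evidence and falls back to distal reads only when no
proximal read qualifies; the per-read table keeps everything for
inspection.

# Statistics

* **Segregation** — chi-square goodness of fit of genotype-class counts
  against a Mendelian ratio (`1:1`, `1:2:1`), `df = k - 1`.
* **SNP association** — per SNP, a 2x2 table of alternative vs reference
  allele counts by phenotype group (alleles = 2 x accessions), two-sided
  Fisher exact test, Benjamini-Hochberg q-values across the panel.
  Allele-based rather than genotype-based tables were chosen because the
  screen compares allele frequencies; monomorphic SNPs are assigned p = 1
  and flagged rather than dropped, keeping the multiplicity correction
  honest. Sidedness is not dictated by the study design; two-sided is the
  neutral choice, with the standard "probability of the observed table or
  anything rarer" tie rule.
* **Co-segregation** — flat must be H1H2, round H1H1, aborted H2H2;
  no-calls are reported separately and never counted as discordant.

# Expression screen

Counts are TPM-normalized (`rate = count/length`, scaled to 1e6 per
sample). Per gene, the log2 fold change of group-mean TPM (pseudocount 1)
is combined with a Welch t test on `log2(TPM + 1)` and BH q-values; a gene
passes at `|log2FC| > 2` and `q < 0.1`. Two choices deserve comment:

* The test is a deliberately simple mean/variance screen, not a
  negative-binomial count model with dispersion shrinkage. The package's
  claim is recovery of planted effects under its own generator — validated
  in the test suite — not reproduction of a specific published gene list.
* The fold-change threshold is interpreted as a plain pseudocounted log2
  ratio of group means. The FDR cut-off is 0.1 by default and
  config-exposed, since published thresholds for this kind of screen vary
  (0.05 is also common).

Zero-variance genes (identical values in both groups) get p = 1 rather
than NaN. qPCR relative expression uses the standard `2^-ddCt` formula.

# The simulators

The generators define the study conditions the tests run under:

* **Reference / locus** — i.i.d. bases at a configurable GC fraction
  (default 0.4, plant-genome-like); the default desk-scale locus is 30 kb
  with a 20-kb inversion `[5000, 25000)`, scaled down from the
  megabase-scale original so that a full diploid genotyping panel runs in
  seconds per accession. The ACA motif is planted upstream of `pb` so the
  construction precondition holds by design.
* **Crosses** — each offspring draws one uniformly random allele per
  parent. Phenotype is a deterministic function of genotype (flat fully
  dominant, H2H2 aborted): every reported cross and cultivar panel shows
  complete penetrance, so no penetrance parameter is modelled.
* **Short reads** — uniform fragments from a uniformly chosen haplotype,
  `round(coverage * (lenA + lenB) / (4 * readLen))` pairs, normal insert
  sizes, mate 2 reverse-complemented, i.i.d. substitution errors (defaults
  30x, 150 bp, 0.5% error — typical resequencing depth; published
  genotyping gives no per-accession figures). Quality strings are constant
  Phred 30 because classification ignores quality. No indels, no
  platform-specific error profile, no duplicates.
* **Long reads** — single-end, normal lengths clamped to
  `[200, haplotype]` (default mean 3 kb), uniform start and strand. Reads
  from H2 crossing a junction carry the orientation switch by
  construction.
* **SNP panel** — dosages binomial(2, group frequency) per accession; the
  bundled screen mirrors a 63-SNP panel with one planted
  0.9-vs-0.1-frequency SNP among nulls at 0.5.
* **Expression** — negative-binomial counts, log-normal base means,
  common dispersion (default 0.05), library-size scaling, one planted
  activated gene. NB with common dispersion is the standard count model
  for bulk RNA-seq; the original study does not state a noise model.

Every simulator is bit-reproducible given a seed. What passing tests show
is recovery of truth under these idealized conditions; real data add
mapping ambiguity, indel errors, coverage biases and incomplete penetrance
that the generators deliberately omit.

# Numerical and scale choices

Problem sizes in the test and acceptance runs were picked to exercise the
statistics at meaningful power while keeping a full run desk-scale: 60
accessions (20 per genotype) for genotype recovery, 400 offspring for the
segregation test, 1000 null SNPs for type-I control, 100 seeded replicates
for detection-rate estimates, and a 20-kb inversion for breakpoint
refinement. Tie-breaks are deterministic throughout (smaller coordinate,
plus strand first, uninformative on cross-junction ties), so every
pipeline output is a pure function of its configuration, which the run
manifest's checksums make checkable.

# Known limitations

* Ungapped alignment only; indel-bearing reads near a junction will lose
  matches rather than gap.
* The unmoderated Welch t has limited power at three replicates per group
  once the FDR correction spans a transcriptome-sized panel: the variance
  estimate at n = 3 is itself so noisy (roughly chi-square with two
  degrees of freedom) that even a 5-log2FC effect often cannot reach the
  small per-gene p-value that q < 0.1 across hundreds of genes demands.
  Count-model tests with dispersion shrinkage exist precisely to pool that
  variance information; the acceptance script reports the screen's
  measured detection rate under its simulation conditions rather than
  hiding it.
* The locus and approximate breakpoints are inputs; there is no genome-wide
  inversion discovery.
* The expression screen is not a count-model fit and should not be expected
  to reproduce dispersion-shrinkage DE results on real libraries.
* Distal breakpoint estimates from single reads carry a +/- 2 bp ambiguity
  inherent to the inserted motif; the consensus resolves it via
  proximal-read evidence.
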
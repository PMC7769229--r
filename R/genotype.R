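#' Call a diploid inversion genotype from junction-support counts
#'
#' An allele is deemed present when both of its junctions are supported:
#' H1 requires at least \code{minReads} spanning reads at each of W_PB and
#' W_DB, H2 likewise at M_PB and M_DB. Both alleles present gives H1H2, one
#' gives the corresponding homozygote, neither gives a no-call.
#'
#' @param support a one-row data.frame (or named list) with counts
#'   \code{n_wpb}, \code{n_wdb}, \code{n_mpb}, \code{n_mdb} (see
#'   \code{\link{tallyJunctionSupport}}).
#' @param minReads integer(1) >= 1, spanning reads required per junction.
#' @return A list with \code{genotype} (\code{"H1H1"}, \code{"H1H2"},
#'   \code{"H2H2"} or \code{"no_call"}) and \code{reason} (non-empty only for
#'   no-calls).
#' @examples
#' callGenotype(list(n_wpb = 6, n_wdb = 5, n_mpb = 4, n_mdb = 7))  # H1H2
#' @export
callGenotype <- function(support, minReads = 3L) {
  minReads <- as.integer(minReads)
  if (is.na(minReads) || minReads < 1L) stop("'minReads' must be >= 1")
  h1 <- support$n_wpb >= minReads && support$n_wdb >= minReads
  h2 <- support$n_mpb >= minReads && support$n_mdb >= minReads
  if (h1 && h2) list(genotype = "H1H2", reason = "")
  else if (h1) list(genotype = "H1H1", reason = "")
  else if (h2) list(genotype = "H2H2", reason = "")
  else list(genotype = "no_call", reason = "insufficient junction support")
}

#' Sequencing-based genotyping of read sets
#'
#' Convenience wrapper: classify reads against the junction references,
#' tally spanning support and call the genotype.
#'
#' @param seqs character vector of read sequences (e.g. the \code{seq}
#'   column of \code{\link{simulateShortReads}} output).
#' @param junctions a \linkS4class{JunctionSet}.
#' @param minReads per-junction support threshold.
#' @param k,maxMismatchFrac,minOverhang,minIdentity classification
#'   parameters (see \code{\link{classifyReads}}).
#' @return A one-row data.frame: support counts, \code{genotype},
#'   \code{reason}.
#' @export
genotypeFromReads <- function(seqs, junctions, minReads = 3L, k = 15L,
                              maxMismatchFrac = 0.1, minOverhang = 15L,
                              minIdentity = 0.9) {
  labels <- classifyReads(seqs, junctions, k = k,
                          maxMismatchFrac = maxMismatchFrac,
                          minOverhang = minOverhang,
                          minIdentity = minIdentity)
  support <- tallyJunctionSupport(labels)
  call <- callGenotype(support, minReads)
  cbind(support, genotype = call$genotype, reason = call$reason)
}

## ------------------------------------------------------------------------ PCR

#' Construct a primer pair
#'
#' @param id primer-pair label (conventionally \code{"P1"}, \code{"P2"},
#'   \code{"P3"}).
#' @param fwd forward primer, 5'->3' on the template's plus strand.
#' @param rev reverse primer, 5'->3' on the opposite strand.
#' @param maxAmplicon largest product length considered amplifiable.
#' @param minPrimerLen enforced minimum primer length (lower it only for toy
#'   constructions).
#' @return A list of class \code{"PrimerPair"}.
#' @export
primerPair <- function(id, fwd, rev, maxAmplicon = 2000L,
                       minPrimerLen = 15L) {
  fwd <- toupper(fwd); rev <- toupper(rev)
  if (nchar(fwd) < minPrimerLen || nchar(rev) < minPrimerLen)
    stop("primer length below ", minPrimerLen)
  structure(list(id = id, fwd = fwd, rev = rev,
                 maxAmplicon = as.integer(maxAmplicon)),
            class = "PrimerPair")
}

## All binding sites of 'primer' on the plus strand of 'template', as 0-based
## starts; <= maxMismatches overall and the 3'-terminal 'exact3p' bases exact.
.primerSites <- function(primer, template, maxMismatches, exact3p,
                         threePrimeAtEnd) {
  m <- Biostrings::matchPattern(primer, Biostrings::DNAString(template),
                                max.mismatch = maxMismatches)
  starts <- Biostrings::start(m) - 1L
  if (!length(starts) || maxMismatches == 0L || exact3p == 0L)
    return(starts)
  plen <- nchar(primer)
  keep <- vapply(starts, function(s) {
    site <- substr(template, s + 1L, s + plen)
    if (threePrimeAtEnd)
      substr(site, plen - exact3p + 1L, plen) ==
        substr(primer, plen - exact3p + 1L, plen)
    else
      substr(site, 1L, exact3p) == substr(primer, 1L, exact3p)
  }, logical(1))
  starts[keep]
}

## One template orientation: fwd binds plus strand, rev's complement lies
## downstream. Returns the shortest product length, or NA.
.amplifyOneOrientation <- function(fwd, rev, template, maxMismatches,
                                   maxAmplicon, exact3p) {
  fsites <- .primerSites(fwd, template, maxMismatches, exact3p,
                         threePrimeAtEnd = TRUE)
  if (!length(fsites)) return(NA_integer_)
  rsites <- .primerSites(revComp(rev), template, maxMismatches, exact3p,
                         threePrimeAtEnd = FALSE)
  if (!length(rsites)) return(NA_integer_)
  best <- NA_integer_
  rlen <- nchar(rev)
  flen <- nchar(fwd)
  for (f in fsites) {
    downstream <- rsites[rsites >= f + flen]
    if (!length(downstream)) next
    len <- min(downstream) + rlen - f
    if (len <= maxAmplicon && (is.na(best) || len < best))
      best <- as.integer(len)
  }
  best
}

#' In-silico PCR of a primer pair against a template
#'
#' A product is called present when the forward primer binds the template
#' and the reverse primer's binding site lies downstream on the opposite
#' strand, each with at most \code{maxMismatches} mismatches (3'-terminal
#' \code{exact3p} bases required exact), with product length at most
#' \code{maxAmplicon}. Both template orientations are searched; the shortest
#' valid product is reported.
#'
#' @param primers a \code{\link{primerPair}}.
#' @param template a \linkS4class{GenomeSegment} or DNA string.
#' @param maxMismatches mismatches tolerated per primer site (default 0).
#' @param exact3p number of 3'-terminal primer bases required to match
#'   exactly (default 3; irrelevant when \code{maxMismatches = 0}).
#' @return A list with \code{present} (logical) and \code{ampliconLength}
#'   (integer, NA when absent).
#' @export
insilicoPcr <- function(primers, template, maxMismatches = 0L,
                        exact3p = 3L) {
  stopifnot(inherits(primers, "PrimerPair"))
  tmpl <- if (is(template, "GenomeSegment")) segSeq(template)
          else toupper(as.character(template))
  lens <- c(
    .amplifyOneOrientation(primers$fwd, primers$rev, tmpl,
                           maxMismatches, primers$maxAmplicon, exact3p),
    .amplifyOneOrientation(primers$fwd, primers$rev, revComp(tmpl),
                           maxMismatches, primers$maxAmplicon, exact3p))
  lens <- lens[!is.na(lens)]
  if (length(lens)) list(present = TRUE, ampliconLength = min(lens))
  else list(present = FALSE, ampliconLength = NA_integer_)
}

#' Design the three diagnostic primer pairs for an inversion locus
#'
#' P1 spans the wild proximal breakpoint (amplifies H1 only); P2 spans the
#' mutant proximal junction and P3 the mutant distal junction (each
#' amplifies H2 only). Primers are placed \code{margin} bases away from the
#' junction on either side.
#'
#' @param pair a \linkS4class{HaplotypePair}.
#' @param primerLen primer length in bases.
#' @param margin distance from junction to the nearest primer end.
#' @param maxAmplicon passed to \code{\link{primerPair}}.
#' @return A named list of three \code{PrimerPair} objects (\code{P1},
#'   \code{P2}, \code{P3}).
#' @export
designDiagnosticPrimers <- function(pair, primerLen = 20L, margin = 30L,
                                    maxAmplicon = 2000L) {
  stopifnot(is(pair, "HaplotypePair"))
  h1 <- segSeq(pair@h1); h2 <- segSeq(pair@h2)
  pb <- pair@spec@pb; db <- pair@spec@db
  pb2 <- pair@pb2; db2 <- pair@db2
  need <- margin + primerLen
  if (pb2 < need || db + need > nchar(h1) || db2 - pb2 < need ||
      pb2 + need > pb + (db - pb))
    stop("locus too small for the requested primer placement")
  sub0 <- function(s, from, to) substr(s, from + 1L, to)  # 0-based half-open
  p1f <- sub0(h1, pb2 - need, pb2 - margin)
  p1r <- revComp(sub0(h1, pb + margin, pb + need))
  p2r <- revComp(sub0(h2, pb2 + margin, pb2 + need))
  p3f <- sub0(h2, db2 - need, db2 - margin)
  p3r <- revComp(sub0(h2, db2 + margin, db2 + need))
  list(P1 = primerPair("P1", p1f, p1r, maxAmplicon),
       P2 = primerPair("P2", p1f, p2r, maxAmplicon),
       P3 = primerPair("P3", p3f, p3r, maxAmplicon))
}

#' Call a genotype from a PCR band pattern
#'
#' P1 assays the wild haplotype; P2 and P3 both assay the inverted
#' haplotype and must co-occur. Any other combination is inconsistent.
#'
#' @param p1,p2,p3 \code{"present"} or \code{"absent"}.
#' @return A list with \code{genotype} and \code{reason}.
#' @examples
#' pcrGenotype("present", "present", "present")  # H1H2
#' @export
pcrGenotype <- function(p1, p2, p3) {
  stopifnot(all(c(p1, p2, p3) %in% c("present", "absent")))
  key <- paste(p1, p2, p3)
  switch(key,
    "present absent absent" = list(genotype = "H1H1", reason = ""),
    "present present present" = list(genotype = "H1H2", reason = ""),
    "absent present present" = list(genotype = "H2H2", reason = ""),
    list(genotype = "no_call", reason = "inconsistent band pattern"))
}

#' PCR-based genotyping of a diploid accession
#'
#' Runs \code{\link{insilicoPcr}} for each diagnostic primer pair against
#' both haplotypes; a band is present when either haplotype yields a
#' product.
#'
#' @param acc an \linkS4class{Accession}.
#' @param primers a list of three \code{PrimerPair}s as returned by
#'   \code{\link{designDiagnosticPrimers}}.
#' @param maxMismatches per-primer mismatch tolerance.
#' @return A one-row data.frame with band calls \code{p1}, \code{p2},
#'   \code{p3}, the \code{genotype} and \code{reason}.
#' @export
pcrGenotypeAccession <- function(acc, primers, maxMismatches = 0L) {
  stopifnot(is(acc, "Accession"))
  band <- vapply(primers, function(pp) {
    hit <- insilicoPcr(pp, acc@hapA, maxMismatches)$present ||
      insilicoPcr(pp, acc@hapB, maxMismatches)$present
    if (hit) "present" else "absent"
  }, character(1))
  call <- pcrGenotype(band[["P1"]], band[["P2"]], band[["P3"]])
  data.frame(p1 = band[["P1"]], p2 = band[["P2"]], p3 = band[["P3"]],
             genotype = call$genotype, reason = call$reason)
}

## --------------------------------------------------------- split long reads

.modeInt <- function(x) {
  if (!length(x)) return(NA_integer_)
  tab <- table(x)
  vals <- as.integer(names(tab))
  vals[order(-as.integer(tab), vals)][1L]
}

#' Refine inversion breakpoints from split long reads
#'
#' Each read (and its reverse complement) is split at every index s and the
#' two parts are aligned ungapped — one forward on H1, the other against the
#' reverse complement of H1 — exhaustively over reference placements whose
#' junction-side boundaries fall inside the search windows, maximizing the
#' explained read bases. Because alignment alone cannot identify a
#' breakpoint to the base (junction microhomology ties parses, and the
#' inserted motif can partially match reference), the refiner uses the
#' known indel signature: a distal split may consume \code{insMotif} from
#' the read, and exact ties prefer the parse placing \code{delMotif} at its
#' expected H1 position. Proximal-junction reads estimate \code{u}, the H1
#' coordinate where wild sequence ends before the junction
#' (\code{pb - nchar(delMotif)}, since the deleted bases are unobservable),
#' and \code{v}, the distal breakpoint reached by the inverted segment;
#' distal-junction reads observe the boundary pair (pb, db).
#'
#' @param reads character vector of read sequences, or a data.frame with
#'   columns \code{id} and \code{seq} (e.g. \code{\link{simulateLongReads}}
#'   output).
#' @param h1 the wild haplotype (\linkS4class{GenomeSegment} or string).
#' @param pbWindow,dbWindow integer length-2 vectors, inclusive windows of
#'   candidate boundary coordinates bracketing the proximal and distal
#'   junctions on H1.
#' @param minPart minimum matches required of each read part (default 20);
#'   reads failing it yield no estimate.
#' @param maxMismatchFrac per-part mismatch-fraction ceiling; part
#'   alignments worse than this are rejected so that reads crossing no
#'   junction (e.g. wholly inside the inverted segment) yield no estimate.
#' @param delMotif,insMotif the locus's breakpoint indel signature
#'   (defaults ACA / GA), used for insertion consumption and tie-breaking
#'   as described above; pass empty strings for a signature-free inversion.
#' @return A list with \code{perRead} (data.frame: \code{read_id},
#'   \code{junction} \code{"PB"}/\code{"DB"}, \code{u}, \code{v},
#'   \code{matches_fwd}, \code{matches_rev}) and \code{consensus} (named
#'   integer vector \code{u}, \code{v}; NA when no informative reads).
#' @export
refineBreakpoints <- function(reads, h1, pbWindow, dbWindow, minPart = 20L,
                              maxMismatchFrac = 0.1, delMotif = "ACA",
                              insMotif = "GA") {
  if (is.data.frame(reads)) {
    ids <- reads$id; seqs <- reads$seq
  } else {
    seqs <- as.character(reads)
    ids <- if (!is.null(names(seqs))) names(seqs)
           else sprintf("read_%04d", seq_along(seqs))
  }
  h1seq <- if (is(h1, "GenomeSegment")) segSeq(h1) else toupper(h1)
  stopifnot(length(pbWindow) == 2L, length(dbWindow) == 2L,
            pbWindow[1L] <= pbWindow[2L], dbWindow[1L] <= dbWindow[2L])
  minPart <- max(1L, as.integer(minPart))
  ## Candidate screen: a junction-crossing read must carry sequence from a
  ## breakpoint neighbourhood; reads sharing no exact 16-mer (either strand)
  ## with those neighbourhoods cannot produce a qualifying split and are
  ## skipped before the exhaustive alignment.
  kScreen <- 16L
  pad <- 8L * kScreen
  sub0 <- function(from, to)
    substr(h1seq, max(1L, from + 1L), min(nchar(h1seq), to))
  panel <- c(sub0(pbWindow[1L] - pad, pbWindow[2L] + pad),
             sub0(dbWindow[1L] - pad, dbWindow[2L] + pad))
  ## reads too short for the screen (or near its resolution) go straight
  ## to the exhaustive alignment
  candidate <- nchar(seqs) < 4L * kScreen |
    .cppHasKmer(seqs, panel, kScreen)
  res <- list(found = logical(length(seqs)), junction = integer(length(seqs)),
              u = integer(length(seqs)), v = integer(length(seqs)),
              matches_fwd = integer(length(seqs)),
              matches_rev = integer(length(seqs)))
  if (any(candidate)) {
    sub <- .cppSplitAlign(seqs[candidate], h1seq,
                             as.integer(pbWindow[1L]),
                             as.integer(pbWindow[2L]),
                             as.integer(dbWindow[1L]),
                             as.integer(dbWindow[2L]),
                             minPart, maxMismatchFrac,
                             toupper(delMotif), toupper(insMotif))
    for (f in names(res)) res[[f]][candidate] <- sub[[f]]
  }
  keep <- res$found
  perRead <- data.frame(
    read_id = ids[keep],
    junction = c("PB", "DB")[res$junction[keep] + 1L],
    u = res$u[keep], v = res$v[keep],
    matches_fwd = res$matches_fwd[keep],
    matches_rev = res$matches_rev[keep])
  ## Proximal-junction reads observe both breakpoint-adjacent coordinates
  ## cleanly (u = pb - deletion length, v = db); distal-junction estimates
  ## can be offset by up to the inserted-motif length because the insertion
  ## is alignable to either side of the split. Consensus therefore prefers
  ## proximal-read evidence, falling back to distal reads if none exists.
  pb_ <- perRead$junction == "PB"
  consensus <- if (any(pb_)) {
    c(u = .modeInt(perRead$u[pb_]), v = .modeInt(perRead$v[pb_]))
  } else {
    c(u = NA_integer_, v = .modeInt(perRead$v))
  }
  list(perRead = perRead, consensus = consensus)
}
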
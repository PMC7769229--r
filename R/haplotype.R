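#' Reverse complement of a DNA string
#'
#' Strict A/C/G/T reverse complementation (an involution). Ambiguity codes are
#' rejected: the inversion machinery operates on resolved haplotype sequence.
#'
#' @param seq character(1) DNA over A/C/G/T; may be empty.
#' @return character(1), the reverse complement.
#' @examples
#' revComp("ATGCC")  # "GGCAT"
#' @export
revComp <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (!nzchar(seq)) return("")
  if (grepl("[^ACGT]", seq))
    stop("invalid alphabet: 'seq' may contain only A, C, G, T")
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Build the inverted haplotype H2 from the wild haplotype H1
#'
#' Applies the inversion-with-indel signature: the half-open interval
#' \code{[pb, db)} of H1 is reverse-complemented; the \code{delMotif} bases
#' immediately upstream of \code{pb} are deleted; and \code{insMotif} is
#' inserted between the inverted segment and the downstream flank. With the
#' default ACA/GA signature, H2 is exactly one base shorter than H1.
#'
#' @param h1 a \linkS4class{GenomeSegment}, the wild haplotype.
#' @param spec an \linkS4class{InversionSpec}.
#' @return A \linkS4class{HaplotypePair} with junction coordinates
#'   \code{pb2 = pb - nchar(delMotif)} and
#'   \code{db2 = pb2 + (db - pb) + nchar(insMotif)} on H2.
#' @examples
#' h1 <- GenomeSegment("toy", "TTTTACAATGCCGGGG")
#' pair <- buildInvertedHaplotype(h1, InversionSpec(pb = 7, db = 12))
#' segSeq(invertedHaplotype(pair))  # "TTTTGGCATGAGGGG"
#' @export
buildInvertedHaplotype <- function(h1, spec) {
  stopifnot(is(h1, "GenomeSegment"), is(spec, "InversionSpec"))
  s <- h1@seq
  pb <- spec@pb; db <- spec@db
  dlen <- nchar(spec@delMotif)
  if (pb >= db) stop("invalid spec: pb must be < db")
  if (db > nchar(s)) stop("invalid spec: db exceeds H1 length")
  if (dlen > 0L && substr(s, pb - dlen + 1L, pb) != spec@delMotif)
    stop("precondition failure: H1[", pb - dlen, ", ", pb, ") is '",
         substr(s, pb - dlen + 1L, pb), "', not the deleted motif '",
         spec@delMotif, "'")
  h2seq <- paste0(substr(s, 1L, pb - dlen),
                  revComp(substr(s, pb + 1L, db)),
                  spec@insMotif,
                  substr(s, db + 1L, nchar(s)))
  pb2 <- pb - dlen
  db2 <- pb2 + (db - pb) + nchar(spec@insMotif)
  new("HaplotypePair",
      h1 = h1,
      h2 = GenomeSegment(paste0(h1@id, "_inv"), h2seq, h1@originOffset),
      spec = spec, pb2 = as.integer(pb2), db2 = as.integer(db2))
}

.extractJunction <- function(id, seq, center, flank) {
  len <- nchar(seq)
  start <- max(0L, center - flank)   # 0-based half-open window
  end <- min(len, center + flank)
  new("Junction", id = id, seq = substr(seq, start + 1L, end),
      center = as.integer(center - start), flank = as.integer(flank))
}

#' Build the four breakpoint junction references
#'
#' Extracts \code{2*flank}-wide windows centred on each breakpoint: the wild
#' proximal and distal breakpoints on H1 (\code{W_PB}, \code{W_DB}) and the
#' two novel junctions on H2 (\code{M_PB}, \code{M_DB}). Windows falling off a
#' sequence end are clipped, with the centre index shifted accordingly.
#'
#' @param pair a \linkS4class{HaplotypePair}.
#' @param flank integer(1) >= 1, bases requested on each side of a breakpoint.
#' @return A \linkS4class{JunctionSet}.
#' @export
buildJunctionSet <- function(pair, flank) {
  stopifnot(is(pair, "HaplotypePair"))
  flank <- as.integer(flank)
  if (is.na(flank) || flank < 1L)
    stop("invalid parameter: 'flank' must be an integer >= 1")
  sp <- pair@spec
  js <- list(
    W_PB = .extractJunction("W_PB", pair@h1@seq, sp@pb, flank),
    W_DB = .extractJunction("W_DB", pair@h1@seq, sp@db, flank),
    M_PB = .extractJunction("M_PB", pair@h2@seq, pair@pb2, flank),
    M_DB = .extractJunction("M_DB", pair@h2@seq, pair@db2, flank))
  new("JunctionSet", junctions = js)
}

#' Scan a sequence for IUPAC motifs
#'
#' Reports every position where each motif matches, optionally on both
#' strands. Minus-strand hits are positions where the motif matches the
#' reverse complement of \code{seq}, reported in \code{seq} coordinates.
#' Intended for cis-regulatory element screens of breakpoint-proximal
#' regions (e.g. the TGTCTC auxin-response-element core).
#'
#' @param seq character(1) DNA over A/C/G/T.
#' @param motifs character vector of IUPAC motifs.
#' @param bothStrands logical(1); scan the minus strand too?
#' @return A data.frame with columns \code{motif}, \code{pos} (0-based start
#'   in \code{seq} coordinates) and \code{strand}, sorted by \code{pos} then
#'   strand (\code{+} first).
#' @examples
#' motifScan("AATGTCTCAA", "TGTCTC")
#' @export
motifScan <- function(seq, motifs, bothStrands = FALSE) {
  stopifnot(is.character(seq), length(seq) == 1L, is.character(motifs))
  iupac <- names(Biostrings::IUPAC_CODE_MAP)
  bad <- unique(unlist(strsplit(motifs, "")))
  bad <- setdiff(bad, iupac)
  if (length(bad))
    stop("invalid IUPAC code(s) in motifs: ", paste(bad, collapse = ", "))
  subj <- Biostrings::DNAString(seq)
  len <- nchar(seq)
  rows <- list()
  for (m in motifs) {
    fwd <- Biostrings::matchPattern(m, subj, fixed = FALSE)
    if (length(fwd))
      rows[[length(rows) + 1L]] <- data.frame(
        motif = m, pos = Biostrings::start(fwd) - 1L, strand = "+")
    if (bothStrands) {
      rev <- Biostrings::matchPattern(m, Biostrings::reverseComplement(subj),
                                      fixed = FALSE)
      if (length(rev))
        rows[[length(rows) + 1L]] <- data.frame(
          motif = m, pos = len - Biostrings::end(rev), strand = "-")
    }
  }
  if (!length(rows))
    return(data.frame(motif = character(), pos = integer(),
                      strand = character()))
  out <- do.call(rbind, rows)
  out <- out[order(out$pos, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Protein length implied by a coding-sequence length
#'
#' Number of amino-acid residues encoded by a CDS whose length includes the
#' stop codon: \code{cdsLenBp / 3 - 1}. A 1326-bp CDS encodes 441 residues.
#'
#' @param cdsLenBp integer(1) CDS length in bp, > 3 and divisible by 3.
#' @return integer(1) residue count.
#' @examples
#' cdsToProteinLength(1326)  # 441
#' @export
cdsToProteinLength <- function(cdsLenBp) {
  cdsLenBp <- as.integer(cdsLenBp)
  if (is.na(cdsLenBp) || cdsLenBp <= 3L || cdsLenBp %% 3L != 0L)
    stop("invalid CDS length: must be > 3 and divisible by 3")
  cdsLenBp %/% 3L - 1L
}
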
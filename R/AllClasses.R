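#' @import methods
#' @importFrom stats rbinom rnbinom rnorm runif rlnorm pchisq pt setNames
#'   fisher.test p.adjust
#' @importFrom utils read.delim write.table
#' @useDynLib flatpeach, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

.validDna <- function(x) {
  nzchar(x) && !grepl("[^ACGT]", x)
}

#' GenomeSegment: a labelled DNA segment
#'
#' A minimal container for a contiguous stretch of genomic DNA: an identifier,
#' an uppercase A/C/G/T sequence, and the 0-based coordinate of its first base
#' in an enclosing coordinate system.
#'
#' @slot id character(1) label.
#' @slot seq character(1) uppercase DNA over A/C/G/T.
#' @slot originOffset integer(1), 0-based offset of \code{seq[1]} in the
#'   enclosing coordinate system (0 when the segment is its own system).
#'
#' @examples
#' seg <- GenomeSegment("toy", "TTTTACAATGCCGGGG")
#' segWidth(seg)
#' @export
setClass("GenomeSegment",
  representation(id = "character", seq = "character",
                 originOffset = "integer"),
  prototype(id = NA_character_, seq = "", originOffset = 0L))

setValidity("GenomeSegment", function(object) {
  msg <- NULL
  if (length(object@seq) != 1L || !nzchar(object@seq))
    msg <- c(msg, "'seq' must be a single non-empty string")
  else if (grepl("[^ACGT]", object@seq))
    msg <- c(msg, "'seq' may contain only A, C, G, T")
  if (length(object@originOffset) != 1L || is.na(object@originOffset) ||
      object@originOffset < 0L)
    msg <- c(msg, "'originOffset' must be a single integer >= 0")
  if (is.null(msg)) TRUE else msg
})

#' @param id character(1) label.
#' @param seq character(1) DNA string; lowercase is uppercased.
#' @param originOffset integer(1), 0-based.
#' @rdname GenomeSegment-class
#' @export
GenomeSegment <- function(id, seq, originOffset = 0L) {
  new("GenomeSegment", id = as.character(id), seq = toupper(as.character(seq)),
      originOffset = as.integer(originOffset))
}

#' InversionSpec: breakpoints and indel signature of an inversion
#'
#' Describes an inversion of the half-open interval \code{[pb, db)} of a wild
#' haplotype, together with the short deletion found immediately upstream of
#' the proximal breakpoint and the short insertion placed at the distal
#' junction of the inverted haplotype. Coordinates are 0-based.
#'
#' @slot pb integer(1) proximal breakpoint (0-based, half-open).
#' @slot db integer(1) distal breakpoint.
#' @slot delMotif character(1) bases deleted at \code{[pb - nchar(delMotif), pb)}
#'   (default \code{"ACA"}); may be empty.
#' @slot insMotif character(1) bases inserted between the inverted segment and
#'   the downstream flank (default \code{"GA"}); may be empty.
#'
#' @export
setClass("InversionSpec",
  representation(pb = "integer", db = "integer",
                 delMotif = "character", insMotif = "character"))

setValidity("InversionSpec", function(object) {
  msg <- NULL
  if (object@pb - nchar(object@delMotif) < 0L)
    msg <- c(msg, "'pb' must leave room for the deleted motif upstream")
  if (object@pb >= object@db)
    msg <- c(msg, "'pb' must be strictly less than 'db'")
  for (s in c(object@delMotif, object@insMotif))
    if (grepl("[^ACGT]", s))
      msg <- c(msg, "indel motifs must be (possibly empty) A/C/G/T strings")
  if (is.null(msg)) TRUE else msg
})

#' @param pb,db integer breakpoints, 0-based half-open.
#' @param delMotif,insMotif DNA strings (possibly empty).
#' @rdname InversionSpec-class
#' @export
InversionSpec <- function(pb, db, delMotif = "ACA", insMotif = "GA") {
  new("InversionSpec", pb = as.integer(pb), db = as.integer(db),
      delMotif = toupper(delMotif), insMotif = toupper(insMotif))
}

#' HaplotypePair: wild and inverted haplotypes of one locus
#'
#' Holds the wild haplotype H1, the inverted haplotype H2 produced by
#' \code{\link{buildInvertedHaplotype}}, the inversion specification, and the
#' H2 coordinates of the two novel junctions: \code{pb2}, where the retained
#' upstream flank meets the inverted segment, and \code{db2}, where the
#' inserted motif meets the downstream flank.
#'
#' @slot h1,h2 \linkS4class{GenomeSegment}.
#' @slot spec \linkS4class{InversionSpec}.
#' @slot pb2,db2 integer(1) junction coordinates on H2 (0-based boundaries).
#'
#' @export
setClass("HaplotypePair",
  representation(h1 = "GenomeSegment", h2 = "GenomeSegment",
                 spec = "InversionSpec", pb2 = "integer", db2 = "integer"))

setValidity("HaplotypePair", function(object) {
  sp <- object@spec
  msg <- NULL
  expLen <- nchar(object@h1@seq) - nchar(sp@delMotif) + nchar(sp@insMotif)
  if (nchar(object@h2@seq) != expLen)
    msg <- c(msg, "H2 length inconsistent with H1 and the indel signature")
  if (object@pb2 != sp@pb - nchar(sp@delMotif))
    msg <- c(msg, "pb2 must equal pb - nchar(delMotif)")
  if (object@db2 != object@pb2 + (sp@db - sp@pb) + nchar(sp@insMotif))
    msg <- c(msg, "db2 inconsistent with pb2 and the inverted-segment length")
  if (is.null(msg)) TRUE else msg
})

#' Junction: a breakpoint-centred reference window
#'
#' A short sequence window centred on a haplotype breakpoint, used as the
#' alignment target for junction-spanning reads. \code{center} is the 0-based
#' boundary index of the breakpoint within \code{seq}; windows clipped at a
#' sequence end keep their true centre index.
#'
#' @slot id one of \code{W_PB}, \code{W_DB}, \code{M_PB}, \code{M_DB}.
#' @slot seq character(1) DNA.
#' @slot center integer(1), 0 < center < nchar(seq).
#' @slot flank integer(1) requested flank length.
#'
#' @export
setClass("Junction",
  representation(id = "character", seq = "character",
                 center = "integer", flank = "integer"))

setValidity("Junction", function(object) {
  msg <- NULL
  if (!object@id %in% c("W_PB", "W_DB", "M_PB", "M_DB"))
    msg <- c(msg, "'id' must be one of W_PB, W_DB, M_PB, M_DB")
  if (!.validDna(object@seq)) msg <- c(msg, "'seq' must be non-empty A/C/G/T")
  if (object@center <= 0L || object@center >= nchar(object@seq))
    msg <- c(msg, "'center' must lie strictly inside 'seq'")
  if (nchar(object@seq) > 2L * object@flank)
    msg <- c(msg, "'seq' cannot exceed 2*flank")
  if (is.null(msg)) TRUE else msg
})

#' JunctionSet: the four diagnostic junctions of an inversion locus
#'
#' Exactly four \linkS4class{Junction} windows — wild proximal (\code{W_PB}),
#' wild distal (\code{W_DB}), mutant proximal (\code{M_PB}) and mutant distal
#' (\code{M_DB}) — sharing one flank size.
#'
#' @slot junctions named list of four \linkS4class{Junction} objects.
#'
#' @export
setClass("JunctionSet", representation(junctions = "list"))

setValidity("JunctionSet", function(object) {
  js <- object@junctions
  ids <- vapply(js, function(j) j@id, character(1))
  msg <- NULL
  if (!setequal(ids, c("W_PB", "W_DB", "M_PB", "M_DB")) || length(js) != 4L)
    msg <- c(msg, "need exactly one junction per id W_PB, W_DB, M_PB, M_DB")
  if (length(unique(vapply(js, function(j) j@flank, integer(1)))) != 1L)
    msg <- c(msg, "all junction flanks must be equal")
  if (!identical(names(js), unname(ids)))
    msg <- c(msg, "junction list names must match junction ids")
  if (is.null(msg)) TRUE else msg
})

#' Accession: a diploid individual at the inversion locus
#'
#' A diploid accession carries two haplotypes drawn from \{H1, H2\} and a
#' fruit phenotype fully determined by its genotype: heterozygotes (H1H2) set
#' flat fruit, H1H1 homozygotes set round fruit, and H2H2 homozygotes abort
#' their fruit early in development.
#'
#' @slot id character(1).
#' @slot genotype one of \code{H1H1}, \code{H1H2}, \code{H2H2}.
#' @slot hapA,hapB \linkS4class{GenomeSegment}.
#' @slot phenotype one of \code{round}, \code{flat}, \code{aborted}.
#'
#' @export
setClass("Accession",
  representation(id = "character", genotype = "character",
                 hapA = "GenomeSegment", hapB = "GenomeSegment",
                 phenotype = "character"))

.phenotypeOf <- function(genotype) {
  switch(genotype, H1H1 = "round", H1H2 = "flat", H2H2 = "aborted",
         stop("unknown genotype: ", genotype))
}

setValidity("Accession", function(object) {
  msg <- NULL
  if (!object@genotype %in% c("H1H1", "H1H2", "H2H2"))
    msg <- c(msg, "'genotype' must be H1H1, H1H2 or H2H2")
  else if (!identical(object@phenotype, .phenotypeOf(object@genotype)))
    msg <- c(msg, "phenotype must follow genotype (round/flat/aborted)")
  if (is.null(msg)) TRUE else msg
})

#' Construct an Accession from a HaplotypePair and a genotype
#'
#' @param pair a \linkS4class{HaplotypePair}.
#' @param genotype \code{"H1H1"}, \code{"H1H2"} or \code{"H2H2"}.
#' @param id character(1) label.
#' @return An \linkS4class{Accession}; the phenotype is derived from the
#'   genotype (complete dominance of flat; homozygous-H2 abortion).
#' @examples
#' pair <- buildInvertedHaplotype(
#'   GenomeSegment("toy", "TTTTACAATGCCGGGG"),
#'   InversionSpec(pb = 7, db = 12))
#' makeAccession(pair, "H1H2", "acc1")
#' @export
makeAccession <- function(pair, genotype, id) {
  stopifnot(is(pair, "HaplotypePair"))
  alleles <- switch(genotype,
    H1H1 = list(pair@h1, pair@h1),
    H1H2 = list(pair@h1, pair@h2),
    H2H2 = list(pair@h2, pair@h2),
    stop("'genotype' must be H1H1, H1H2 or H2H2"))
  new("Accession", id = as.character(id), genotype = genotype,
      hapA = alleles[[1L]], hapB = alleles[[2L]],
      phenotype = .phenotypeOf(genotype))
}

## ------------------------------------------------------------------ accessors

#' @describeIn GenomeSegment-class sequence string.
#' @param x,object a GenomeSegment.
#' @export
segSeq <- function(x) x@seq

#' @describeIn GenomeSegment-class segment width in bases.
#' @export
segWidth <- function(x) nchar(x@seq)

#' @describeIn GenomeSegment-class identifier.
#' @export
segId <- function(x) x@id

#' @describeIn HaplotypePair-class wild haplotype H1.
#' @param x,object a HaplotypePair.
#' @export
wildHaplotype <- function(x) x@h1

#' @describeIn HaplotypePair-class inverted haplotype H2.
#' @export
invertedHaplotype <- function(x) x@h2

#' @describeIn HaplotypePair-class the \linkS4class{InversionSpec}.
#' @export
inversionSpec <- function(x) x@spec

#' @describeIn JunctionSet-class extract one junction by id.
#' @param x a JunctionSet.
#' @param id junction id.
#' @export
junction <- function(x, id) {
  stopifnot(is(x, "JunctionSet"), id %in% names(x@junctions))
  x@junctions[[id]]
}

#' @describeIn JunctionSet-class junction ids.
#' @export
junctionIds <- function(x) names(x@junctions)

#' @describeIn JunctionSet-class the common flank size.
#' @export
junctionFlank <- function(x) x@junctions[[1L]]@flank

## ----------------------------------------------------------------------- show

setMethod("show", "GenomeSegment", function(object) {
  s <- object@seq
  prev <- if (nchar(s) > 40L) paste0(substr(s, 1L, 37L), "...") else s
  cat("GenomeSegment '", object@id, "': ", nchar(s), " bp, offset ",
      object@originOffset, "\n  ", prev, "\n", sep = "")
})

setMethod("show", "InversionSpec", function(object) {
  cat("InversionSpec: invert [", object@pb, ", ", object@db, "), del '",
      object@delMotif, "' upstream of pb, ins '", object@insMotif,
      "' at distal junction\n", sep = "")
})

setMethod("show", "HaplotypePair", function(object) {
  cat("HaplotypePair: H1 ", segWidth(object@h1), " bp, H2 ",
      segWidth(object@h2), " bp; junctions on H2 at pb2=", object@pb2,
      ", db2=", object@db2, "\n", sep = "")
})

setMethod("show", "JunctionSet", function(object) {
  cat("JunctionSet (flank ", junctionFlank(object), "):\n", sep = "")
  for (j in object@junctions)
    cat("  ", j@id, ": ", nchar(j@seq), " bp, center ", j@center, "\n",
        sep = "")
})

setMethod("show", "Accession", function(object) {
  cat("Accession '", object@id, "': genotype ", object@genotype,
      ", phenotype ", object@phenotype, "\n", sep = "")
})
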
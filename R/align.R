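.junctionSeqs <- function(junctions) {
  vapply(junctions@junctions, function(j) j@seq, character(1))
}

.junctionCenters <- function(junctions) {
  vapply(junctions@junctions, function(j) j@center, integer(1))
}

#' Ungapped seed-and-extend alignment of a read against junction references
#'
#' Exact k-mer seeds locate candidate diagonals on each junction sequence and
#' each strand; each diagonal is extended ungapped in both directions, taking
#' the extension that maximizes matches while the cumulative mismatch
#' fraction of the aligned span stays at or below \code{maxMismatchFrac}.
#' The maximal-matches hit per junction is returned. Deterministic.
#'
#' @param read character(1) read sequence (or a named element of a simulated
#'   read table).
#' @param junctions a \linkS4class{JunctionSet}.
#' @param k integer(1) seed length, >= 8.
#' @param maxMismatchFrac numeric(1) in [0, 1).
#' @return A data.frame of hits with columns \code{junction_id},
#'   \code{ref_start}/\code{ref_end} (0-based half-open on the junction),
#'   \code{read_start}/\code{read_end} (original read orientation),
#'   \code{strand}, \code{matches}, \code{mismatches}, \code{identity}.
#'   Reads shorter than \code{k} yield an empty frame with a warning.
#' @export
seedAndExtend <- function(read, junctions, k = 15L, maxMismatchFrac = 0.1) {
  stopifnot(is(junctions, "JunctionSet"))
  k <- as.integer(k)
  if (k < 8L) stop("'k' must be >= 8")
  empty <- data.frame(junction_id = character(), ref_start = integer(),
                      ref_end = integer(), read_start = integer(),
                      read_end = integer(), strand = character(),
                      matches = integer(), mismatches = integer(),
                      identity = numeric())
  if (nchar(read) < k) {
    warning("read shorter than seed length k; no alignment attempted")
    return(empty)
  }
  hits <- .cppSeedExtend(read, unname(.junctionSeqs(junctions)),
                         junctionIds(junctions), k, maxMismatchFrac)
  if (!nrow(hits)) return(empty)
  hits$identity <- hits$matches / (hits$matches + hits$mismatches)
  hits
}

#' Classify one read's hits as junction-spanning support
#'
#' A hit spans its junction when the aligned reference interval contains
#' \code{[center - minOverhang, center + minOverhang)} and its identity is at
#' least \code{minIdentity}. Among spanning hits the unique one with maximal
#' matches wins; a tie across different junctions, or no spanning hit, is
#' uninformative (conservative: a read sitting entirely in flank shared by
#' wild and mutant haplotypes supports neither).
#'
#' @param hits data.frame from \code{\link{seedAndExtend}} (one read).
#' @param junctions the \linkS4class{JunctionSet} the hits refer to.
#' @param minOverhang integer(1) minimum bases on each side of the centre.
#' @param minIdentity numeric(1) minimum hit identity.
#' @return A list with \code{label} (a junction id or
#'   \code{"uninformative"}), \code{left_overhang} and \code{right_overhang}
#'   (NA when uninformative).
#' @export
classifyRead <- function(hits, junctions, minOverhang = 15L,
                         minIdentity = 0.9) {
  stopifnot(is(junctions, "JunctionSet"))
  out <- list(label = "uninformative", left_overhang = NA_integer_,
              right_overhang = NA_integer_)
  if (!nrow(hits)) return(out)
  centers <- .junctionCenters(junctions)
  cc <- centers[hits$junction_id]
  spans <- hits$ref_start <= cc - minOverhang &
    hits$ref_end >= cc + minOverhang & hits$identity >= minIdentity
  hs <- hits[spans, , drop = FALSE]
  if (!nrow(hs)) return(out)
  top <- hs[hs$matches == max(hs$matches), , drop = FALSE]
  if (length(unique(top$junction_id)) != 1L) return(out)
  w <- top[1L, ]
  c0 <- centers[[w$junction_id]]
  list(label = w$junction_id,
       left_overhang = as.integer(c0 - w$ref_start),
       right_overhang = as.integer(w$ref_end - c0))
}

#' Classify many reads at once
#'
#' Batch version of \code{\link{seedAndExtend}} + \code{\link{classifyRead}},
#' run entirely in compiled code.
#'
#' @param seqs character vector of read sequences.
#' @param junctions a \linkS4class{JunctionSet}.
#' @param k,maxMismatchFrac seed-and-extend parameters.
#' @param minOverhang,minIdentity spanning-call parameters.
#' @return character vector of labels (junction id or
#'   \code{"uninformative"}), one per read.
#' @export
classifyReads <- function(seqs, junctions, k = 15L, maxMismatchFrac = 0.1,
                          minOverhang = 15L, minIdentity = 0.9) {
  stopifnot(is(junctions, "JunctionSet"))
  k <- as.integer(k)
  if (k < 8L) stop("'k' must be >= 8")
  ids <- junctionIds(junctions)
  lab <- .cppClassifyBatch(seqs, unname(.junctionSeqs(junctions)),
                           unname(.junctionCenters(junctions)), k,
                           maxMismatchFrac, as.integer(minOverhang),
                           minIdentity)
  c(ids, "uninformative")[lab + 1L]
}

#' Tally junction-spanning support labels
#'
#' @param labels character vector of labels from \code{\link{classifyReads}}.
#' @return A one-row data.frame with counts \code{n_wpb}, \code{n_wdb},
#'   \code{n_mpb}, \code{n_mdb} and \code{n_uninformative}.
#' @export
tallyJunctionSupport <- function(labels) {
  data.frame(n_wpb = sum(labels == "W_PB"),
             n_wdb = sum(labels == "W_DB"),
             n_mpb = sum(labels == "M_PB"),
             n_mdb = sum(labels == "M_DB"),
             n_uninformative = sum(labels == "uninformative"))
}
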
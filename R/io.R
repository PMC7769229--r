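## Plain-text interchange: FASTA for haplotypes and junction references,
## four-line FASTQ for simulated reads, headered TSV (UTF-8, unquoted) for
## tables. All round trips are lossless.

#' Write GenomeSegments or a JunctionSet to FASTA
#'
#' Sequences wrap at 80 columns. Junction headers carry
#' \code{center=<int> flank=<int>} key-value tags.
#'
#' @param x a \linkS4class{GenomeSegment}, a list of them, or a
#'   \linkS4class{JunctionSet}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeFasta <- function(x, path) {
  if (is(x, "GenomeSegment")) x <- list(x)
  if (is(x, "JunctionSet")) {
    seqs <- .junctionSeqs(x)
    names(seqs) <- sprintf("%s center=%d flank=%d", junctionIds(x),
                           .junctionCenters(x), junctionFlank(x))
  } else {
    seqs <- vapply(x, segSeq, character(1))
    names(seqs) <- vapply(x, segId, character(1))
  }
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path,
                              width = 80L)
  invisible(path)
}

#' Read FASTA into GenomeSegments
#'
#' Lowercase bases are uppercased with a warning.
#'
#' @param path FASTA file.
#' @return Named list of \linkS4class{GenomeSegment} objects (names are the
#'   first whitespace-delimited header token).
#' @export
readFasta <- function(path) {
  lines <- readLines(path)
  if (any(grepl("[acgt]", lines[!startsWith(lines, ">")])))
    warning("lowercase bases uppercased on read")
  set <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  segs <- lapply(seq_along(set), function(i)
    GenomeSegment(ids[i], as.character(set[[i]])))
  setNames(segs, ids)
}

#' Read a junction-reference FASTA back into a JunctionSet
#'
#' Expects the header tags written by \code{\link{writeFasta}}.
#'
#' @param path FASTA file of four junction sequences.
#' @return A \linkS4class{JunctionSet}.
#' @export
readJunctionFasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  heads <- names(set)
  ids <- sub("\\s.*$", "", heads)
  center <- as.integer(sub(".*center=(\\d+).*", "\\1", heads))
  flank <- as.integer(sub(".*flank=(\\d+).*", "\\1", heads))
  if (any(is.na(center)) || any(is.na(flank)))
    stop("parse error: junction headers need center= and flank= tags")
  js <- lapply(seq_along(set), function(i)
    new("Junction", id = ids[i], seq = as.character(set[[i]]),
        center = center[i], flank = flank[i]))
  new("JunctionSet", junctions = setNames(js, ids))
}

#' Write simulated reads as FASTQ
#'
#' One four-line record per read. Paired reads are interleaved in input
#' order; mate is appended to the id as \code{/1}, \code{/2} when present.
#'
#' @param reads data.frame with columns \code{id}, \code{seq}, \code{qual}
#'   and optionally \code{mate}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeFastq <- function(reads, path) {
  ids <- reads$id
  if (!is.null(reads$mate) && !all(reads$mate == "none"))
    ids <- paste0(ids, "/", reads$mate)
  writeLines(as.vector(rbind(paste0("@", ids), reads$seq, "+", reads$qual)),
             path)
  invisible(path)
}

#' Read a FASTQ file
#'
#' @param path FASTQ file (four-line records).
#' @return data.frame with columns \code{id}, \code{seq}, \code{qual}.
#' @export
readFastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L)
    stop("parse error: FASTQ length not a multiple of 4 at line ",
         length(lines))
  at <- seq(1L, length(lines), by = 4L)
  bad <- at[!startsWith(lines[at], "@")]
  if (length(bad))
    stop("parse error: missing '@' header at line ", bad[1L])
  data.frame(id = sub("^@", "", lines[at]), seq = lines[at + 1L],
             qual = lines[at + 3L])
}

#' Write a data.frame as headered TSV
#'
#' Tab-separated, header row, UTF-8, no quoting, no row names.
#'
#' @param df data.frame.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a headered TSV, checking required columns
#'
#' @param path TSV file.
#' @param requiredCols character vector of column names that must exist.
#' @return data.frame.
#' @export
readTsv <- function(path, requiredCols = NULL) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   check.names = FALSE)
  missing <- setdiff(requiredCols, names(df))
  if (length(missing))
    stop("schema error: missing column(s) ", paste(missing, collapse = ", "))
  df
}
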
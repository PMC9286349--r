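## Reading, writing, normalising and indexing protein sequence databases,
## plus reversed-sequence decoy generation.

#' Read a protein database from FASTA
#'
#' Parses a FASTA file into a \linkS4class{Proteome}. The accession is the
#' header token up to the first whitespace; sequences are upper-cased. Records
#' containing letters outside the 20-letter amino-acid alphabet (e.g. B, J, O,
#' U, X, Z) are rejected with the offending line number, or silently dropped
#' when \code{dropInvalid = TRUE}, so that the splice mapper's alphabet stays
#' closed.
#'
#' @param path Path to a FASTA file.
#' @param ilCollapsed Logical: mark the result as already I/L-collapsed
#'   (validated; default \code{FALSE}).
#' @param dropInvalid Drop records with non-canonical residues instead of
#'   raising an error (default \code{FALSE}).
#' @return A \linkS4class{Proteome}.
#' @seealso [writeProteomeFasta()], [collapseIL()]
#' @export
readProteomeFasta <- function(path, ilCollapsed = FALSE, dropInvalid = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0L) stop("empty FASTA file: ", path)
  acc <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(acc))
    stop("duplicate accession in ", path, ": ", acc[duplicated(acc)][1L])
  ch <- toupper(as.character(seqs))
  bad <- grepl(sprintf("[^%s]", paste(AA_ALPHABET20, collapse = "")), ch)
  if (any(bad)) {
    if (dropInvalid) {
      ch <- ch[!bad]
      acc <- acc[!bad]
      if (length(ch) == 0L)
        stop("all records in ", path, " contain non-canonical residues")
    } else {
      ln <- .badResidueLine(path, acc[bad][1L])
      stop(sprintf(
        "non-amino-acid character in record '%s' (line %d of %s)",
        acc[bad][1L], ln, path))
    }
  }
  Proteome(setNames(ch, acc), ilCollapsed = ilCollapsed)
}

## locate the first offending sequence line of a record, for error reporting
.badResidueLine <- function(path, accession) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^>", lines)
  recStart <- hdr[sub("\\s.*$", "", sub("^>", "", lines[hdr])) == accession][1L]
  if (is.na(recStart)) return(NA_integer_)
  i <- recStart + 1L
  pat <- sprintf("[^%s]", paste(AA_ALPHABET20, collapse = ""))
  while (i <= length(lines) && !startsWith(lines[i], ">")) {
    if (grepl(pat, toupper(lines[i]))) return(i)
    i <- i + 1L
  }
  recStart
}

#' Write a Proteome to FASTA
#'
#' Sequences are wrapped at 60 columns.
#'
#' @param proteome A \linkS4class{Proteome}.
#' @param path Output file path.
#' @return Invisibly, \code{path}.
#' @export
writeProteomeFasta <- function(proteome, path) {
  stopifnot(is(proteome, "Proteome"))
  Biostrings::writeXStringSet(proteome@seqs, filepath = path, width = 60L)
  invisible(path)
}

#' @describeIn collapseIL Collapse a whole proteome; sets the
#'   \code{ilCollapsed} flag.
#' @export
setMethod("collapseIL", "Proteome", function(x) {
  ch <- chartr("I", "L", as.character(x@seqs))
  Proteome(setNames(ch, names(x@seqs)), ilCollapsed = TRUE)
})

#' @describeIn collapseIL Collapse peptide strings.
#' @export
setMethod("collapseIL", "character", function(x) chartr("I", "L", x))

#' @describeIn makeDecoy Whole-protein reversal of every entry.
#' @export
setMethod("makeDecoy", "Proteome", function(x, tag = DECOY_TAG) {
  rev <- Biostrings::reverse(x@seqs)
  names(rev) <- paste0(tag, names(x@seqs))
  Proteome(setNames(as.character(rev), names(rev)),
           ilCollapsed = x@ilCollapsed)
})

#' Build a substring occurrence index
#'
#' @param proteome A non-empty \linkS4class{Proteome}.
#' @return A \linkS4class{SubstringIndex}.
#' @examples
#' idx <- buildIndex(Proteome(c(P1 = "ACAC")))
#' lookupOccurrences(idx, "AC")
#' @export
buildIndex <- function(proteome) {
  stopifnot(is(proteome, "Proteome"))
  if (length(proteome) == 0L) stop("cannot index an empty proteome")
  ch <- as.character(proteome@seqs)
  w <- nchar(ch)
  ## offsets of each entry within the separator-joined subject
  offsets <- cumsum(c(1L, head(w + 1L, -1L)))
  new("SubstringIndex", accessions = names(proteome@seqs),
      widths = as.integer(w), offsets = as.integer(offsets),
      subject = paste(ch, collapse = "-"),
      ilCollapsed = proteome@ilCollapsed)
}

#' Look up all exact occurrences of a peptide
#'
#' Returns every occurrence of \code{peptide} across the indexed sequences in
#' 0-based half-open coordinates, sorted by (entry order, start) — exactly the
#' result of a naive scan over every sequence.
#'
#' @param index A \linkS4class{SubstringIndex}.
#' @param peptide A single peptide string.
#' @return data.frame with columns \code{accession}, \code{entry} (integer
#'   position of the entry in the database), \code{start}, \code{end}.
#' @export
lookupOccurrences <- function(index, peptide) {
  stopifnot(is(index, "SubstringIndex"), is.character(peptide),
            length(peptide) == 1L)
  if (nchar(peptide) == 0L) stop("empty query peptide")
  pos <- .indexPositions(index, peptide)
  entry <- findInterval(pos, index@offsets)
  start0 <- pos - index@offsets[entry]
  data.frame(accession = index@accessions[entry], entry = entry,
             start = start0, end = start0 + nchar(peptide),
             stringsAsFactors = FALSE)
}

## global 1-based subject positions of a query; integer(0) when absent.
## Non-alphabet queries cannot occur (and must not match the separator).
.indexPositions <- function(index, peptide) {
  if (grepl("[^A-Z]", peptide)) return(integer(0))
  m <- gregexpr(peptide, index@subject, fixed = TRUE)[[1L]]
  if (m[1L] == -1L) integer(0) else as.integer(m)
}

## occurrences of `peptide` restricted to one entry, local 0-based starts
.entryStarts <- function(seqChar, peptide) {
  m <- gregexpr(peptide, seqChar, fixed = TRUE)[[1L]]
  if (m[1L] == -1L) integer(0) else as.integer(m) - 1L
}
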
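## Plain-text interchange formats: MGF peak lists, de novo candidate tables,
## PSM tables and answer keys. All writers emit deterministic, fixed-format
## text so that seeded runs are byte-reproducible.

#' Write spectra to an MGF file
#'
#' The spectrum id is carried in the TITLE field; m/z values are written with
#' five decimals and intensities with two.
#'
#' @param spectra A list of \linkS4class{Spectrum} (or a single one).
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeMgf <- function(spectra, path) {
  if (is(spectra, "Spectrum")) spectra <- list(spectra)
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (sp in spectra) {
    pk <- peaks(sp)
    writeLines(c("BEGIN IONS",
                 paste0("TITLE=", spectrumId(sp)),
                 sprintf("PEPMASS=%.5f", precursorMz(sp)),
                 sprintf("CHARGE=%d+", precursorCharge(sp)),
                 sprintf("%.5f %.2f", pk[, 1L], pk[, 2L]),
                 "END IONS"), con)
  }
  invisible(path)
}

#' Read spectra from an MGF file
#'
#' @param path Path to an MGF file.
#' @return List of \linkS4class{Spectrum}.
#' @export
readMgf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  begins <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(begins) != length(ends) || any(ends < begins))
    stop("malformed MGF file: ", path)
  lapply(seq_along(begins), function(i) {
    block <- lines[(begins[i] + 1L):(ends[i] - 1L)]
    hdr <- grepl("=", block, fixed = TRUE)
    kv <- strsplit(block[hdr], "=", fixed = TRUE)
    keys <- vapply(kv, `[[`, character(1L), 1L)
    vals <- vapply(kv, function(x) paste(x[-1L], collapse = "="),
                   character(1L))
    pkLines <- block[!hdr & nzchar(block)]
    pk <- if (length(pkLines)) {
      do.call(rbind, lapply(strsplit(pkLines, "[ \t]+"), function(x)
        as.numeric(x[1:2])))
    } else matrix(numeric(), ncol = 2L)
    charge <- as.integer(sub("\\+$", "", vals[keys == "CHARGE"][1L]))
    Spectrum(vals[keys == "TITLE"][1L],
             as.numeric(strsplit(vals[keys == "PEPMASS"][1L], " ")[[1L]][1L]),
             charge, pk)
  })
}

#' Write a de novo candidate table
#'
#' Tab-separated with columns \code{spectrum_id}, \code{rank},
#' \code{sequence}, \code{alc}, \code{lcs} (semicolon-joined per-residue
#' scores), mirroring the structure of an exported all-candidates table.
#'
#' @param denovo Candidate data.frame.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeDeNovoTable <- function(denovo, path) {
  write.table(denovo[, c("spectrum_id", "rank", "sequence", "alc", "lcs")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a de novo candidate table
#'
#' Validates that each candidate has one LCS value per residue and that the
#' ALC equals the mean LCS within rounding (tolerance 0.51).
#'
#' @param path Path to a tab-separated candidate table.
#' @return Candidate data.frame.
#' @export
readDeNovoTable <- function(path) {
  dn <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c(spectrum_id = "character",
                                  sequence = "character",
                                  lcs = "character"))
  vals <- .lcsValues(dn$lcs)
  nl <- lengths(vals)
  if (any(nl != nchar(dn$sequence))) {
    i <- which(nl != nchar(dn$sequence))[1L]
    stop("row ", i, ": ", nl[i], " LCS values for a ", nchar(dn$sequence[i]),
         "-residue sequence")
  }
  mu <- vapply(vals, mean, numeric(1L))
  off <- abs(mu - dn$alc) > 0.51
  if (any(off))
    stop("row ", which(off)[1L], ": ALC ", dn$alc[which(off)[1L]],
         " does not match the mean LCS ", round(mu[which(off)[1L]], 2L))
  dn
}

#' Write / read a PSM table
#'
#' Tab-separated: \code{spectrum_id}, \code{peptide}, \code{score},
#' \code{is_decoy}, \code{accession}, \code{assigned_category}. Externally
#' produced PSM tables in this layout can be benchmarked exactly like the
#' built-in engine's output.
#'
#' @param psms PSM data.frame.
#' @param path File path.
#' @return \code{writePsmTable}: invisibly \code{path};
#'   \code{readPsmTable}: PSM data.frame.
#' @export
writePsmTable <- function(psms, path) {
  cols <- intersect(c("spectrum_id", "peptide", "score", "is_decoy",
                      "accession", "assigned_category", "n_matched",
                      "n_theoretical"), names(psms))
  df <- psms[, cols, drop = FALSE]
  if ("score" %in% cols) df$score <- sprintf("%.6f", df$score)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writePsmTable
#' @export
readPsmTable <- function(path) {
  psms <- read.delim(path, stringsAsFactors = FALSE,
                     colClasses = c(spectrum_id = "character",
                                    peptide = "character"))
  psms$is_decoy <- as.logical(psms$is_decoy)
  psms$score <- as.numeric(psms$score)
  psms
}

#' Write / read an answer key
#'
#' Tab-separated: \code{spectrum_id}, \code{peptide}, \code{category}
#' (\code{NONSPLICED}, \code{CIS} or \code{TRAPPING}).
#'
#' @param answerKey Answer key data.frame.
#' @param path File path.
#' @return \code{writeAnswerKey}: invisibly \code{path};
#'   \code{readAnswerKey}: data.frame.
#' @export
writeAnswerKey <- function(answerKey, path) {
  write.table(answerKey[, c("spectrum_id", "peptide", "category")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeAnswerKey
#' @export
readAnswerKey <- function(path) {
  read.delim(path, stringsAsFactors = FALSE,
             colClasses = c(spectrum_id = "character"))
}
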
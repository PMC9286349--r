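#' Accessions of a sequence container
#' @param x A \linkS4class{Proteome}, \linkS4class{SubstringIndex} or
#'   \linkS4class{TargetDatabase}.
#' @return Character vector of accessions.
#' @export
setGeneric("accessions", function(x) standardGeneric("accessions"))

#' Protein sequences as a character vector
#' @param x A \linkS4class{Proteome} or \linkS4class{TargetDatabase}.
#' @return Named character vector of sequences.
#' @export
setGeneric("proteinSequences", function(x) standardGeneric("proteinSequences"))

#' Is the database I/L-collapsed?
#' @param x A \linkS4class{Proteome} or \linkS4class{SubstringIndex}.
#' @return Logical scalar.
#' @export
setGeneric("isIlCollapsed", function(x) standardGeneric("isIlCollapsed"))

#' Replace isoleucine by leucine
#'
#' Removes the I/L mass redundancy that MS cannot resolve by rewriting every
#' \code{I} as \code{L}. Idempotent.
#'
#' @param x A \linkS4class{Proteome} or character vector of peptides.
#' @return An object of the same class, I-free.
#' @export
setGeneric("collapseIL", function(x) standardGeneric("collapseIL"))

#' Reversed-sequence decoy database
#'
#' Reverses every target sequence whole-protein and prefixes accessions with
#' \code{"DECOY_"}, for target-decoy FDR estimation.
#'
#' @param x A \linkS4class{Proteome}.
#' @param tag Accession prefix (default \code{"DECOY_"}).
#' @return A \linkS4class{Proteome} of the same size.
#' @export
setGeneric("makeDecoy", function(x, tag = DECOY_TAG) standardGeneric("makeDecoy"))

#' @rdname GroundTruthBundle-class
#' @param x A \linkS4class{GroundTruthBundle}.
#' @export
setGeneric("constructedDb", function(x) standardGeneric("constructedDb"))

#' @rdname GroundTruthBundle-class
#' @export
setGeneric("categoryLabels", function(x) standardGeneric("categoryLabels"))

#' @rdname GroundTruthBundle-class
#' @export
setGeneric("plantRecords", function(x) standardGeneric("plantRecords"))

#' @rdname GroundTruthBundle-class
#' @export
setGeneric("verificationReport", function(x) standardGeneric("verificationReport"))

#' @rdname TargetDatabase-class
#' @param x A \linkS4class{TargetDatabase}.
#' @export
setGeneric("referenceProteome", function(x) standardGeneric("referenceProteome"))

#' @rdname TargetDatabase-class
#' @export
setGeneric("splicedEntries", function(x) standardGeneric("splicedEntries"))

#' @rdname TargetDatabase-class
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

## ---- Proteome methods -----------------------------------------------------

#' @describeIn Proteome-class Number of entries.
#' @param x A \code{Proteome}.
#' @export
setMethod("length", "Proteome", function(x) length(x@seqs))

#' @describeIn Proteome-class Entry accessions.
#' @export
setMethod("accessions", "Proteome", function(x) names(x@seqs))

#' @describeIn Proteome-class Sequences as a named character vector.
#' @export
setMethod("proteinSequences", "Proteome",
          function(x) setNames(as.character(x@seqs), names(x@seqs)))

#' @describeIn Proteome-class I/L collapse state.
#' @export
setMethod("isIlCollapsed", "Proteome", function(x) x@ilCollapsed)

setMethod("show", "Proteome", function(object) {
  cat(sprintf("Proteome: %d entr%s, %d residues%s\n",
              length(object), if (length(object) == 1L) "y" else "ies",
              sum(Biostrings::width(object@seqs)),
              if (object@ilCollapsed) " (I/L-collapsed)" else ""))
  if (length(object) > 0L) {
    n <- min(3L, length(object))
    for (i in seq_len(n)) {
      s <- as.character(object@seqs[[i]])
      cat(sprintf("  %s  %s%s\n", names(object@seqs)[i],
                  substr(s, 1L, 40L), if (nchar(s) > 40L) "..." else ""))
    }
    if (length(object) > n) cat(sprintf("  ... and %d more\n", length(object) - n))
  }
})

setMethod("accessions", "SubstringIndex", function(x) x@accessions)
setMethod("isIlCollapsed", "SubstringIndex", function(x) x@ilCollapsed)

setMethod("show", "SubstringIndex", function(object) {
  cat(sprintf("SubstringIndex over %d entries, %d residues%s\n",
              length(object@accessions), sum(object@widths),
              if (object@ilCollapsed) " (I/L-collapsed)" else ""))
})

setMethod("show", "MapperParams", function(object) {
  cat(sprintf(paste0("MapperParams: maxIntervening=%d, minReactantLen=%d, ",
                     "allowOverlap=%s, longCisAsTrans=%s\n"),
              object@maxIntervening, object@minReactantLen,
              object@allowOverlap, object@longCisAsTrans))
})

#' @describeIn Classification-class Winning category.
#' @param x A \code{Classification}.
#' @export
setGeneric("category", function(x) standardGeneric("category"))

#' @describeIn Classification-class Winning category.
#' @export
setMethod("category", "Classification", function(x) x@category)

#' @describeIn Classification-class Supporting explanations (data.frame).
#' @export
setGeneric("explanations", function(x) standardGeneric("explanations"))

#' @describeIn Classification-class Supporting explanations.
#' @export
setMethod("explanations", "Classification", function(x) x@explanations)

setMethod("show", "Classification", function(object) {
  cat(sprintf("Classification of '%s': %s (%d explanation%s)\n",
              object@peptide, object@category, nrow(object@explanations),
              if (nrow(object@explanations) == 1L) "" else "s"))
})

## ---- GroundTruthBundle methods -------------------------------------------

#' @describeIn GroundTruthBundle-class The constructed database.
#' @export
setMethod("constructedDb", "GroundTruthBundle", function(x) x@constructedDb)

#' @describeIn GroundTruthBundle-class Intended category per peptide.
#' @export
setMethod("categoryLabels", "GroundTruthBundle", function(x) x@labels)

#' @describeIn GroundTruthBundle-class Planting records.
#' @export
setMethod("plantRecords", "GroundTruthBundle", function(x) x@plants)

#' @describeIn GroundTruthBundle-class Intended-vs-observed report.
#' @export
setMethod("verificationReport", "GroundTruthBundle", function(x) x@verification)

setMethod("show", "GroundTruthBundle", function(object) {
  tab <- table(factor(object@labels,
                      levels = c("NONSPLICED", "CIS", "TRAPPING")))
  ok <- if (nrow(object@verification)) sum(object@verification$ok) else 0L
  cat(sprintf(paste0("GroundTruthBundle: %d targets ",
                     "(%d non-spliced, %d cis, %d trapping), ",
                     "%d/%d verified\n"),
              length(object@labels), tab[["NONSPLICED"]], tab[["CIS"]],
              tab[["TRAPPING"]], ok, nrow(object@verification)))
  cat(sprintf("  constructed db: %d entries, %d residues\n",
              length(object@constructedDb),
              sum(nchar(proteinSequences(object@constructedDb)))))
})

## ---- TargetDatabase methods ----------------------------------------------

#' @describeIn TargetDatabase-class The reference proteome.
#' @export
setMethod("referenceProteome", "TargetDatabase", function(x) x@reference)

#' @describeIn TargetDatabase-class In-silico spliced entries.
#' @export
setMethod("splicedEntries", "TargetDatabase", function(x) x@splicedEntries)

#' @describeIn TargetDatabase-class Candidate provenance table.
#' @export
setMethod("provenance", "TargetDatabase", function(x) x@provenance)

setMethod("show", "TargetDatabase", function(object) {
  cat(sprintf(paste0("TargetDatabase (%s): %d reference entries + ",
                     "%d in-silico entries (%d candidates)\n"),
              if (nzchar(object@mode)) object@mode else "empty",
              length(object@reference), length(object@splicedEntries),
              nrow(object@provenance)))
})

setMethod("show", "Spectrum", function(object) {
  cat(sprintf("Spectrum '%s': precursor %.4f m/z (%d+), %d peaks\n",
              object@spectrumId, object@precursorMz, object@charge,
              nrow(object@peaks)))
})

#' Spectrum peak matrix
#' @param x A \linkS4class{Spectrum}.
#' @return Two-column matrix (mz, intensity).
#' @export
setGeneric("peaks", function(x) standardGeneric("peaks"))

#' @describeIn Spectrum-class Peak matrix.
#' @export
setMethod("peaks", "Spectrum", function(x) x@peaks)

#' Spectrum identifier
#' @param x A \linkS4class{Spectrum}.
#' @return Character scalar.
#' @export
setGeneric("spectrumId", function(x) standardGeneric("spectrumId"))

#' @describeIn Spectrum-class Identifier.
#' @export
setMethod("spectrumId", "Spectrum", function(x) x@spectrumId)

#' Precursor m/z
#' @param x A \linkS4class{Spectrum}.
#' @return Numeric scalar.
#' @export
setGeneric("precursorMz", function(x) standardGeneric("precursorMz"))

#' @describeIn Spectrum-class Precursor m/z.
#' @export
setMethod("precursorMz", "Spectrum", function(x) x@precursorMz)

#' Precursor charge
#' @param x A \linkS4class{Spectrum}.
#' @return Integer scalar.
#' @export
setGeneric("precursorCharge", function(x) standardGeneric("precursorCharge"))

#' @describeIn Spectrum-class Charge state.
#' @export
setMethod("precursorCharge", "Spectrum", function(x) x@charge)
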
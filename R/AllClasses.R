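#' @import methods
#' @importClassesFrom Biostrings AAStringSet
#' @importFrom stats median quantile rnorm runif rpois setNames phyper rlnorm
#' @importFrom utils read.delim write.table head tail
NULL

## 20 canonical residues; the I-free alphabet is what an I/L-collapsed
## database is written in.
AA_ALPHABET20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                   "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
AA_ALPHABET19 <- setdiff(AA_ALPHABET20, "I")

## Monoisotopic residue masses (Da) and physical constants used for b/y-ion
## arithmetic throughout.
AA_MONO_MASS <- c(
  G =  57.02146, A =  71.03711, S =  87.03203, P =  97.05276,
  V =  99.06841, T = 101.04768, C = 103.00919, L = 113.08406,
  I = 113.08406, N = 114.04293, D = 115.02694, Q = 128.05858,
  K = 128.09496, E = 129.04259, M = 131.04049, H = 137.05891,
  F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931)
PROTON_MASS <- 1.00727646688
WATER_MASS  <- 18.0105646863

DECOY_TAG   <- "DECOY_"
SPLICED_TAG <- "SPLICED_"

## Category priority used by the explanation hierarchy:
## non-spliced > cis > trans > none.
CATEGORY_PRIORITY <- c(NONSPLICED = 3L, CIS = 2L, TRANS = 1L, NONE = 0L)

#' Proteome: an ordered protein sequence database
#'
#' Wraps a named \link[Biostrings]{AAStringSet} of protein sequences over the
#' 20-letter amino-acid alphabet, together with a flag recording whether
#' isoleucine has been collapsed onto leucine (I/L redundancy removal).
#'
#' @slot seqs An \code{AAStringSet} with unique, non-empty names (accessions).
#' @slot ilCollapsed Logical; if \code{TRUE} no sequence contains \code{I}.
#'
#' @seealso [readProteomeFasta()], [collapseIL()], [makeDecoy()], [buildIndex()]
#' @export
setClass("Proteome",
  representation(seqs = "AAStringSet", ilCollapsed = "logical"))

setValidity("Proteome", function(object) {
  s <- object@seqs
  nm <- names(s)
  if (length(s) > 0L && (is.null(nm) || anyNA(nm) || any(nm == "")))
    return("all entries must be named with an accession")
  if (anyDuplicated(nm))
    return(sprintf("duplicate accession: %s", nm[duplicated(nm)][1L]))
  if (length(object@ilCollapsed) != 1L || is.na(object@ilCollapsed))
    return("'ilCollapsed' must be TRUE or FALSE")
  ch <- as.character(s)
  if (any(nchar(ch) == 0L))
    return("empty sequence(s) present")
  bad <- grepl(sprintf("[^%s]", paste(AA_ALPHABET20, collapse = "")), ch)
  if (any(bad))
    return(sprintf("non-canonical residue in entry '%s'", nm[bad][1L]))
  if (object@ilCollapsed && any(grepl("I", ch, fixed = TRUE)))
    return("proteome flagged I/L-collapsed but contains isoleucine")
  TRUE
})

#' Construct a Proteome
#'
#' @param sequences A named character vector or \code{AAStringSet} of protein
#'   sequences (upper-cased on input).
#' @param ilCollapsed Logical flag; set \code{TRUE} only for databases whose
#'   isoleucines have already been replaced by leucine.
#' @return A \linkS4class{Proteome}.
#' @examples
#' p <- Proteome(c(P1 = "MKLLPETGAL", P2 = "AAAA"))
#' @export
Proteome <- function(sequences = character(), ilCollapsed = FALSE) {
  if (is(sequences, "XStringSet")) {
    seqs <- Biostrings::AAStringSet(toupper(as.character(sequences)))
    names(seqs) <- names(sequences)
  } else {
    seqs <- Biostrings::AAStringSet(toupper(as.character(sequences)))
    names(seqs) <- names(sequences)
  }
  new("Proteome", seqs = seqs, ilCollapsed = isTRUE(ilCollapsed))
}

#' Substring occurrence index over a proteome
#'
#' Supports exact-occurrence lookup of a query peptide across all protein
#' sequences. Occurrences are reported in 0-based half-open coordinates,
#' ordered by (entry order, start). Internally the sequences are joined with a
#' separator character so a single C-level fixed-string scan serves each query.
#'
#' @slot accessions Character vector of entry accessions, in database order.
#' @slot widths Integer vector of sequence lengths.
#' @slot offsets Integer vector: 1-based start of each entry in \code{subject}.
#' @slot subject Single string: all sequences joined with \code{"-"}.
#' @slot ilCollapsed Logical, inherited from the proteome.
#' @seealso [buildIndex()], [lookupOccurrences()]
#' @export
setClass("SubstringIndex",
  representation(accessions = "character", widths = "integer",
                 offsets = "integer", subject = "character",
                 ilCollapsed = "logical"))

#' Splice mapper parameters
#'
#' @slot maxIntervening Maximum number of residues allowed between the two
#'   reactant occurrences of a cis explanation (default 25).
#' @slot minReactantLen Minimum reactant length (default 1).
#' @slot allowOverlap If \code{TRUE}, cis explanations whose reactant
#'   occurrences overlap (negative intervening length) are admitted.
#' @slot longCisAsTrans If \code{TRUE}, same-protein reactant pairs whose
#'   intervening length exceeds \code{maxIntervening} count as trans
#'   explanations; by default they are not explanations at all.
#' @export
setClass("MapperParams",
  representation(maxIntervening = "integer", minReactantLen = "integer",
                 allowOverlap = "logical", longCisAsTrans = "logical"))

setValidity("MapperParams", function(object) {
  if (object@maxIntervening < 0L) return("'maxIntervening' must be >= 0")
  if (object@minReactantLen < 1L) return("'minReactantLen' must be >= 1")
  TRUE
})

#' Construct splice mapper parameters
#'
#' @param maxIntervening Non-negative integer, residues (default 25).
#' @param minReactantLen Positive integer (default 1).
#' @param allowOverlap Logical (default \code{FALSE}).
#' @param longCisAsTrans Logical (default \code{FALSE}).
#' @return A \linkS4class{MapperParams}.
#' @export
mapperParams <- function(maxIntervening = 25, minReactantLen = 1,
                         allowOverlap = FALSE, longCisAsTrans = FALSE) {
  new("MapperParams", maxIntervening = as.integer(maxIntervening),
      minReactantLen = as.integer(minReactantLen),
      allowOverlap = isTRUE(allowOverlap),
      longCisAsTrans = isTRUE(longCisAsTrans))
}

#' Classification of a peptide against a proteome
#'
#' Result of [classifyPeptide()]: the winning category under the hierarchy
#' non-spliced > cis > trans > none, together with all supporting explanations
#' of that category.
#'
#' @slot peptide The classified peptide sequence.
#' @slot category One of \code{"NONSPLICED"}, \code{"CIS"}, \code{"TRANS"},
#'   \code{"NONE"}.
#' @slot explanations A data.frame of explanations restricted to the winning
#'   category (see [findExplanations()] for columns).
#' @export
setClass("Classification",
  representation(peptide = "character", category = "character",
                 explanations = "data.frame"))

#' Ground-truth construction parameters
#'
#' @slot maxIntervening Maximum intervening length for cis plants/mapping.
#' @slot seed Integer seed, or NA to use the current RNG state.
#' @slot categoryWeights Numeric(3) proportions for the non-spliced, cis and
#'   trapping categories; must sum to 1.
#' @slot maxRetries Maximum resampling attempts per planted peptide.
#' @export
setClass("GroundTruthParams",
  representation(maxIntervening = "integer", seed = "integer",
                 categoryWeights = "numeric", maxRetries = "integer"))

setValidity("GroundTruthParams", function(object) {
  w <- object@categoryWeights
  if (length(w) != 3L || any(w < 0) || abs(sum(w) - 1) > 1e-8)
    return("'categoryWeights' must be three non-negative proportions summing to 1")
  if (object@maxRetries < 1L) return("'maxRetries' must be >= 1")
  if (object@maxIntervening < 1L)
    return("'maxIntervening' must be >= 1 (cis plants need room for an intervening sequence)")
  TRUE
})

#' Construct ground-truth parameters
#'
#' @param maxIntervening Integer (default 25).
#' @param seed Integer seed or \code{NA} (default) to leave the RNG alone.
#' @param categoryWeights Numeric(3), default equal thirds.
#' @param maxRetries Integer (default 100).
#' @return A \linkS4class{GroundTruthParams}.
#' @export
groundTruthParams <- function(maxIntervening = 25, seed = NA,
                              categoryWeights = c(1, 1, 1) / 3,
                              maxRetries = 100) {
  new("GroundTruthParams", maxIntervening = as.integer(maxIntervening),
      seed = as.integer(seed), categoryWeights = as.numeric(categoryWeights),
      maxRetries = as.integer(maxRetries))
}

#' A constructed ground-truth reference database bundle
#'
#' Output of [buildGroundTruth()]: the modified reference database, the
#' intended category of every target peptide, the planting records, and the
#' verification report (intended vs observed category for every target).
#'
#' @slot constructedDb The constructed \linkS4class{Proteome}.
#' @slot labels Named character vector: peptide -> intended category
#'   (\code{"NONSPLICED"}, \code{"CIS"} or \code{"TRAPPING"}).
#' @slot plants data.frame of planting records (one row per target).
#' @slot verification data.frame: peptide, intended, observed, ok.
#' @export
setClass("GroundTruthBundle",
  representation(constructedDb = "Proteome", labels = "character",
                 plants = "data.frame", verification = "data.frame"))

#' A spliced-peptide target database
#'
#' A reference proteome plus in-silico entries holding retained de novo
#' candidate sequences, as produced by the AP or MBS selection workflows.
#'
#' @slot reference The reference \linkS4class{Proteome}.
#' @slot splicedEntries \code{AAStringSet} of appended in-silico entries
#'   (accessions carry the \code{"SPLICED_"} prefix).
#' @slot provenance data.frame mapping each retained candidate to its spectrum,
#'   sequence, mapped category and selection score.
#' @slot mode \code{"AP"} or \code{"MBS"} (or \code{""} for an empty build).
#' @export
setClass("TargetDatabase",
  representation(reference = "Proteome", splicedEntries = "AAStringSet",
                 provenance = "data.frame", mode = "character"))

#' A single MS2 spectrum
#'
#' @slot spectrumId Spectrum identifier (carried in the MGF TITLE).
#' @slot precursorMz Precursor m/z.
#' @slot charge Precursor charge (1--4).
#' @slot peaks Two-column numeric matrix (\code{mz}, \code{intensity}),
#'   sorted by m/z.
#' @export
setClass("Spectrum",
  representation(spectrumId = "character", precursorMz = "numeric",
                 charge = "integer", peaks = "matrix"))

setValidity("Spectrum", function(object) {
  if (!object@charge %in% 1:4) return("charge must be in 1..4")
  pk <- object@peaks
  if (ncol(pk) != 2L) return("'peaks' must have two columns (mz, intensity)")
  if (nrow(pk) > 0L) {
    if (is.unsorted(pk[, 1L])) return("peaks must be sorted by m/z")
    if (any(pk[, 2L] <= 0)) return("peak intensities must be positive")
  }
  TRUE
})

#' Construct a Spectrum
#'
#' @param spectrumId Identifier string.
#' @param precursorMz Precursor m/z.
#' @param charge Integer charge state 1--4.
#' @param peaks Two-column matrix or data.frame (mz, intensity); reordered by
#'   m/z if needed.
#' @return A \linkS4class{Spectrum}.
#' @export
Spectrum <- function(spectrumId, precursorMz, charge, peaks) {
  pk <- as.matrix(peaks)
  if (length(pk) == 0L) pk <- matrix(numeric(), ncol = 2L)
  colnames(pk) <- c("mz", "intensity")
  pk <- pk[order(pk[, 1L]), , drop = FALSE]
  new("Spectrum", spectrumId = as.character(spectrumId),
      precursorMz = as.numeric(precursorMz), charge = as.integer(charge),
      peaks = pk)
}

#' Search parameters for the stand-in engine
#'
#' @slot precursorTolPpm Precursor mass tolerance in ppm (default 5).
#' @slot fragmentTolDa Fragment match tolerance in Da (default 0.02).
#' @slot peptideLenRange Integer(2): candidate peptide length range,
#'   default 8--15.
#' @export
setClass("SearchParams",
  representation(precursorTolPpm = "numeric", fragmentTolDa = "numeric",
                 peptideLenRange = "integer"))

setValidity("SearchParams", function(object) {
  if (object@precursorTolPpm <= 0 || object@fragmentTolDa <= 0)
    return("tolerances must be positive")
  if (length(object@peptideLenRange) != 2L ||
      object@peptideLenRange[1L] > object@peptideLenRange[2L] ||
      object@peptideLenRange[1L] < 2L)
    return("'peptideLenRange' must be an increasing pair of lengths >= 2")
  TRUE
})

#' Construct search parameters
#'
#' Defaults mirror a high-resolution Orbitrap acquisition: 5 ppm precursor and
#' 0.02 Da fragment tolerances, unspecific digestion into 8--15-mers.
#'
#' @param precursorTolPpm Numeric (default 5).
#' @param fragmentTolDa Numeric (default 0.02).
#' @param peptideLenRange Integer(2) (default \code{c(8, 15)}).
#' @return A \linkS4class{SearchParams}.
#' @export
searchParams <- function(precursorTolPpm = 5, fragmentTolDa = 0.02,
                         peptideLenRange = c(8, 15)) {
  new("SearchParams", precursorTolPpm = as.numeric(precursorTolPpm),
      fragmentTolDa = as.numeric(fragmentTolDa),
      peptideLenRange = as.integer(peptideLenRange))
}

#' MS2 spectrum simulation model
#'
#' Parameters of the generative model behind [simulateSpectrum()]: each
#' theoretical singly-charged b/y ion is detected independently with
#' probability \code{fragmentDetectProb} and jittered by a Gaussian of sd
#' \code{mzJitterSd}; a Poisson number of uniform noise peaks is added; peak
#' intensities are log-normal with separate signal and noise parameters.
#'
#' @slot fragmentDetectProb Probability a theoretical fragment is observed.
#' @slot noiseLambda Poisson mean of the noise peak count.
#' @slot noiseMzRange Numeric(2) m/z interval for noise peaks.
#' @slot signalMeanLog,signalSdLog Log-normal parameters for signal intensity.
#' @slot noiseMeanLog,noiseSdLog Log-normal parameters for noise intensity.
#' @slot mzJitterSd Gaussian m/z jitter sd (Da) applied to signal peaks.
#' @slot precursorPpmSd Gaussian jitter (ppm) applied to the precursor m/z.
#' @slot chargeProbs Probabilities of charges 1..4.
#' @export
setClass("SpectrumModel",
  representation(fragmentDetectProb = "numeric", noiseLambda = "numeric",
                 noiseMzRange = "numeric", signalMeanLog = "numeric",
                 signalSdLog = "numeric", noiseMeanLog = "numeric",
                 noiseSdLog = "numeric", mzJitterSd = "numeric",
                 precursorPpmSd = "numeric", chargeProbs = "numeric"))

setValidity("SpectrumModel", function(object) {
  if (object@fragmentDetectProb < 0 || object@fragmentDetectProb > 1)
    return("'fragmentDetectProb' must be in [0,1]")
  if (object@mzJitterSd < 0) return("'mzJitterSd' must be >= 0")
  if (object@noiseLambda < 0) return("'noiseLambda' must be >= 0")
  if (length(object@chargeProbs) != 4L || any(object@chargeProbs < 0))
    return("'chargeProbs' must be four non-negative weights")
  TRUE
})

#' Construct a spectrum model
#'
#' @param fragmentDetectProb Default 0.8: typical b/y ion series coverage of a
#'   well-fragmented HLA-I peptide.
#' @param noiseLambda Mean number of noise peaks (default 30).
#' @param noiseMzRange m/z window for noise (default 200--1500).
#' @param signalMeanLog,signalSdLog Signal log-intensity (default 6, 0.6).
#' @param noiseMeanLog,noiseSdLog Noise log-intensity (default 4, 0.7).
#' @param mzJitterSd Fragment m/z jitter sd in Da (default 0.005, well inside a
#'   0.02 Da match tolerance).
#' @param precursorPpmSd Precursor m/z jitter in ppm (default 1).
#' @param chargeProbs Charge state distribution over 1..4; HLA-I 8--15-mers are
#'   mostly 2+ (default \code{c(0.2, 0.6, 0.2, 0)}).
#' @return A \linkS4class{SpectrumModel}.
#' @export
spectrumModel <- function(fragmentDetectProb = 0.8, noiseLambda = 30,
                          noiseMzRange = c(200, 1500), signalMeanLog = 6,
                          signalSdLog = 0.6, noiseMeanLog = 4,
                          noiseSdLog = 0.7, mzJitterSd = 0.005,
                          precursorPpmSd = 1,
                          chargeProbs = c(0.2, 0.6, 0.2, 0)) {
  new("SpectrumModel", fragmentDetectProb = as.numeric(fragmentDetectProb),
      noiseLambda = as.numeric(noiseLambda),
      noiseMzRange = as.numeric(noiseMzRange),
      signalMeanLog = as.numeric(signalMeanLog),
      signalSdLog = as.numeric(signalSdLog),
      noiseMeanLog = as.numeric(noiseMeanLog),
      noiseSdLog = as.numeric(noiseSdLog),
      mzJitterSd = as.numeric(mzJitterSd),
      precursorPpmSd = as.numeric(precursorPpmSd),
      chargeProbs = as.numeric(chargeProbs))
}

#' De novo sequencing error model
#'
#' Governs [simulateDenovo()]: with probability \code{pCorrectRank1} the true
#' sequence is the rank-1 candidate; erroneous candidates are derived from the
#' true sequence by single-residue substitutions, adjacent-pair swaps or
#' isobaric replacements; per-residue local confidence scores (LCS) are drawn
#' around a signal or error mean and, when \code{lcsErrorLocalization} is set,
#' depressed at the erroneous positions. The candidate ALC is always the mean
#' of its LCS values.
#'
#' @slot pCorrectRank1 Probability the true sequence is rank 1.
#' @slot substitutionWeights Named numeric(3) weights over
#'   \code{c("single", "swap", "isobaric")}.
#' @slot lcsSignalMean,lcsSignalSd Per-residue LCS distribution of correct
#'   sequence stretches.
#' @slot lcsErrorDepressionMean,lcsErrorDepressionSd Depression applied to the
#'   LCS of erroneous residues.
#' @slot lcsErrorLocalization Logical: depress LCS at erroneous positions.
#' @export
setClass("DeNovoErrorModel",
  representation(pCorrectRank1 = "numeric", substitutionWeights = "numeric",
                 lcsSignalMean = "numeric", lcsSignalSd = "numeric",
                 lcsErrorDepressionMean = "numeric",
                 lcsErrorDepressionSd = "numeric",
                 lcsErrorLocalization = "logical"))

setValidity("DeNovoErrorModel", function(object) {
  if (object@pCorrectRank1 < 0 || object@pCorrectRank1 > 1)
    return("'pCorrectRank1' must be in [0,1]")
  w <- object@substitutionWeights
  if (length(w) != 3L || any(w < 0) || sum(w) <= 0)
    return("'substitutionWeights' must be three non-negative weights")
  TRUE
})

#' Construct a de novo error model
#'
#' @param pCorrectRank1 Default 0.7: de novo engines recover the full correct
#'   sequence for most but not all confidently fragmented HLA-I peptides.
#' @param substitutionWeights Weights over single substitution, adjacent swap
#'   and isobaric replacement (default \code{c(0.4, 0.4, 0.2)}).
#' @param lcsSignalMean,lcsSignalSd Default 90 and 8: local confidence of
#'   correctly sequenced residues is high on average but bursty, with
#'   individual residues regularly dipping below 80 even in correct
#'   candidates (which is what makes a per-residue confidence filter much
#'   stricter than a mean-confidence filter).
#' @param lcsErrorDepressionMean,lcsErrorDepressionSd Default 25 and 6.
#' @param lcsErrorLocalization Default \code{TRUE}.
#' @return A \linkS4class{DeNovoErrorModel}.
#' @export
deNovoErrorModel <- function(pCorrectRank1 = 0.7,
                             substitutionWeights = c(single = 0.4,
                                                     swap = 0.4,
                                                     isobaric = 0.2),
                             lcsSignalMean = 90, lcsSignalSd = 8,
                             lcsErrorDepressionMean = 25,
                             lcsErrorDepressionSd = 6,
                             lcsErrorLocalization = TRUE) {
  w <- as.numeric(substitutionWeights)
  names(w) <- c("single", "swap", "isobaric")
  new("DeNovoErrorModel", pCorrectRank1 = as.numeric(pCorrectRank1),
      substitutionWeights = w,
      lcsSignalMean = as.numeric(lcsSignalMean),
      lcsSignalSd = as.numeric(lcsSignalSd),
      lcsErrorDepressionMean = as.numeric(lcsErrorDepressionMean),
      lcsErrorDepressionSd = as.numeric(lcsErrorDepressionSd),
      lcsErrorLocalization = isTRUE(lcsErrorLocalization))
}
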
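## Evaluation of PSM sets against answer keys: precision/recall curves per
## peptide category, misassignment cross-tables for trapping spectra,
## FDR-vs-PSM curves, and spectrum/peptide feature computation.

## Kyte-Doolittle hydropathy values
KYTE_DOOLITTLE <- c(
  A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I =  4.5, L =  3.8, K = -3.9, M =  1.9, F =  2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2)

## category a correct PSM of this true category must be assigned
.expectedAssigned <- function(trueCategory) {
  ifelse(trueCategory == "TRAPPING", "TRANS", trueCategory)
}

.checkKey <- function(psms, answerKey) {
  missing <- setdiff(psms$spectrum_id, answerKey$spectrum_id)
  if (length(missing) > 0L)
    stop("spectrum absent from the answer key: ", missing[1L])
}

## per-PSM correctness: sequence identity after I/L collapse AND category
## agreement with the true category
.correctFlags <- function(psms, answerKey) {
  i <- match(psms$spectrum_id, answerKey$spectrum_id)
  trueSeq <- collapseIL(answerKey$peptide[i])
  trueCat <- answerKey$category[i]
  correct <- !psms$is_decoy &
    collapseIL(psms$peptide) == trueSeq &
    !is.na(psms$assigned_category) &
    psms$assigned_category == .expectedAssigned(trueCat)
  list(correct = correct, trueCat = trueCat)
}

#' Precision/recall curves per peptide category
#'
#' For each category and score threshold, precision is the number of
#' correctly identified PSMs over all PSMs assigned to that category, and
#' recall the number of correct PSMs over the number of true PSMs of the
#' category. A PSM counts as correct when its sequence equals the answer-key
#' peptide after I/L collapse and its assigned category agrees with the true
#' category. Thresholds with no assigned PSM yield no precision point (the
#' row is dropped); the additional \code{"ALL"} category counts every PSM
#' (decoys included) regardless of category.
#'
#' @param psms PSM data.frame (see [searchSpectra()]).
#' @param answerKey data.frame \code{spectrum_id}, \code{peptide},
#'   \code{category}; must cover every PSM spectrum.
#' @param thresholds Numeric score thresholds.
#' @param categories Categories to report (default non-spliced and cis).
#' @return data.frame: \code{category}, \code{threshold}, \code{n_assigned},
#'   \code{n_correct}, \code{n_true}, \code{precision}, \code{recall}.
#' @export
precisionRecall <- function(psms, answerKey,
                            thresholds = defaultThresholds(),
                            categories = c("NONSPLICED", "CIS")) {
  .checkKey(psms, answerKey)
  fl <- .correctFlags(psms, answerKey)
  out <- list()
  for (cat in categories) {
    nTrue <- sum(answerKey$category == cat)
    sel <- !psms$is_decoy & !is.na(psms$assigned_category) &
      psms$assigned_category == cat
    for (t in thresholds) {
      at <- sel & psms$score >= t
      nAssigned <- sum(at)
      nCorrect <- sum(at & fl$correct & fl$trueCat == cat)
      if (nAssigned == 0L) next
      out[[length(out) + 1L]] <- data.frame(
        category = cat, threshold = t, n_assigned = nAssigned,
        n_correct = nCorrect, n_true = nTrue,
        precision = nCorrect / nAssigned,
        recall = if (nTrue > 0L) nCorrect / nTrue else NA_real_)
    }
  }
  ## overall: decoys included in the assignment count
  for (t in thresholds) {
    at <- psms$score >= t
    nAssigned <- sum(at)
    if (nAssigned == 0L) next
    nCorrect <- sum(at & fl$correct)
    out[[length(out) + 1L]] <- data.frame(
      category = "ALL", threshold = t, n_assigned = nAssigned,
      n_correct = nCorrect, n_true = nrow(answerKey),
      precision = nCorrect / nAssigned,
      recall = nCorrect / nrow(answerKey))
  }
  if (length(out) == 0L)
    return(data.frame(category = character(), threshold = numeric(),
                      n_assigned = integer(), n_correct = integer(),
                      n_true = integer(), precision = numeric(),
                      recall = numeric()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Misassignment cross-table
#'
#' Counts target PSMs at or above a threshold, cross-tabulated by true
#' category (rows: NONSPLICED, CIS, TRAPPING) and assigned category (columns:
#' NONSPLICED, CIS, TRANS, NONE). The TRAPPING row shows how many spectra of
#' deliberately unidentifiable peptides were wrongly assigned non-spliced or
#' cis-spliced sequences.
#'
#' @param psms PSM data.frame.
#' @param answerKey Answer key covering every PSM spectrum.
#' @param threshold Score threshold.
#' @return Integer matrix.
#' @export
misassignmentTable <- function(psms, answerKey, threshold) {
  .checkKey(psms, answerKey)
  keep <- !psms$is_decoy & psms$score >= threshold
  sub <- psms[keep, , drop = FALSE]
  i <- match(sub$spectrum_id, answerKey$spectrum_id)
  trueCat <- factor(answerKey$category[i],
                    levels = c("NONSPLICED", "CIS", "TRAPPING"))
  assigned <- factor(ifelse(is.na(sub$assigned_category), "NONE",
                            sub$assigned_category),
                     levels = c("NONSPLICED", "CIS", "TRANS", "NONE"))
  as.matrix(table(true = trueCat, assigned = assigned))
}

#' FDR vs assigned-PSM curve
#'
#' For each threshold, the number of assigned target PSMs paired with the
#' decoy-estimated FDR, the machinery behind FDR-vs-PSM curves used to judge
#' whether an engine's estimated FDR rises gently or steeply with yield.
#'
#' @param psms PSM data.frame including decoy hits.
#' @param thresholds Ascending numeric thresholds.
#' @return data.frame: \code{threshold}, \code{n_assigned} (target PSMs),
#'   \code{fdr_percent}.
#' @export
fdrPsmCurve <- function(psms, thresholds = defaultThresholds()) {
  sw <- thresholdSweep(psms, thresholds)
  data.frame(threshold = sw$threshold, n_assigned = sw$n_target,
             fdr_percent = sw$fdr_percent)
}

#' Spectrum and peptide features
#'
#' Relative ion coverage (matched theoretical b/y ions over \code{2(n-1)}),
#' signal-to-noise ratio (median intensity of fragment-matched peaks over
#' median intensity of unmatched peaks; \code{Inf} when every peak matches),
#' peptide length, and mean Kyte-Doolittle hydropathy.
#'
#' @param spectrum A \linkS4class{Spectrum}.
#' @param peptide The peptide to evaluate against the spectrum.
#' @param params A \linkS4class{SearchParams} (fragment tolerance).
#' @return One-row data.frame: \code{ion_coverage}, \code{snr},
#'   \code{peptide_length}, \code{hydrophobicity}.
#' @export
spectrumFeatures <- function(spectrum, peptide, params = searchParams()) {
  pk <- peaks(spectrum)
  frag <- theoreticalFragments(peptide)
  tol <- params@fragmentTolDa
  nMatched <- .matchedCount(frag, pk[, 1L], tol)
  coverage <- nMatched / length(frag)
  if (nrow(pk) > 0L) {
    hi <- findInterval(pk[, 1L] + tol, frag)
    lo <- findInterval(pk[, 1L] - tol, frag)
    peakMatched <- hi > lo
    snr <- if (all(peakMatched)) Inf
    else if (!any(peakMatched)) NA_real_
    else median(pk[peakMatched, 2L]) / median(pk[!peakMatched, 2L])
  } else snr <- NA_real_
  chars <- strsplit(peptide, "")[[1L]]
  data.frame(ion_coverage = coverage, snr = snr,
             peptide_length = nchar(peptide),
             hydrophobicity = mean(KYTE_DOOLITTLE[chars]))
}
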
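## A pluggable stand-in database search engine: unspecific digestion of the
## target+decoy database into length-bounded substrings, a precomputed
## precursor mass index, a hypergeometric shared-peak-count score, and the
## target-decoy FDR estimator FDR = 100 * 2D / (T + D).

#' Monoisotopic peptide mass
#'
#' @param peptide Peptide sequence over the canonical alphabet.
#' @return Neutral monoisotopic mass in Da (residue masses + water).
#' @export
peptideMass <- function(peptide) {
  chars <- strsplit(peptide, "")[[1L]]
  m <- AA_MONO_MASS[chars]
  if (anyNA(m)) stop("unknown residue in '", peptide, "'")
  sum(m) + WATER_MASS
}

#' Theoretical b/y fragment m/z values
#'
#' Singly-charged b- and y-ion m/z for all prefix/suffix lengths 1..n-1,
#' from monoisotopic residue masses. A peptide of length n yields exactly
#' 2(n-1) fragments.
#'
#' @param peptide Peptide sequence.
#' @param charge Retained for interface symmetry; fragments are singly
#'   charged.
#' @return Sorted numeric vector of fragment m/z values, named
#'   \code{b1..b(n-1)}, \code{y1..y(n-1)}.
#' @examples
#' theoreticalFragments("GG")   # b1 58.029, y1 76.039
#' @export
theoreticalFragments <- function(peptide, charge = 1L) {
  n <- nchar(peptide)
  stopifnot(n >= 2L)
  chars <- strsplit(peptide, "")[[1L]]
  m <- AA_MONO_MASS[chars]
  if (anyNA(m)) stop("unknown residue in '", peptide, "'")
  cum <- cumsum(m)
  b <- cum[-n] + PROTON_MASS
  ## suffix masses, shortest suffix (y1) first
  y <- (cum[n] - cum[n - seq_len(n - 1L)]) + WATER_MASS + PROTON_MASS
  out <- c(setNames(b, paste0("b", seq_len(n - 1L))),
           setNames(y, paste0("y", seq_len(n - 1L))))
  sort(out)
}

## number of theoretical fragments matched by at least one spectrum peak
.matchedCount <- function(frag, peakMz, tol) {
  if (length(peakMz) == 0L || length(frag) == 0L) return(0L)
  hi <- findInterval(frag + tol, peakMz)
  lo <- findInterval(frag - tol, peakMz)
  sum(hi > lo)
}

## -log10 hypergeometric tail: population of N m/z bins, K occupied by
## observed peaks, n theoretical fragments drawn, X >= m matched
.hypergeomScore <- function(m, nTheo, nPeaks, mzRange, tol) {
  if (m <= 0L) return(0)
  N <- max(round(mzRange / (2 * tol)), nPeaks, nTheo, 1L)
  K <- min(nPeaks, N)
  p <- phyper(m - 1L, K, N - K, nTheo, lower.tail = FALSE)
  if (p <= 0) p <- .Machine$double.xmin
  -log10(p)
}

#' Score a peptide-spectrum match
#'
#' The score is the negative log10 tail probability of matching \code{m} of
#' the \code{2(n-1)} theoretical b/y fragments by chance, under a
#' hypergeometric model over m/z bins of width twice the fragment tolerance
#' spanning the spectrum's m/z range. Deterministic; higher is better; a
#' match with no shared fragments (or an empty peak list) scores 0.
#'
#' @param spectrum A \linkS4class{Spectrum}.
#' @param peptide Candidate peptide sequence.
#' @param params A \linkS4class{SearchParams}.
#' @return Numeric score.
#' @export
scorePsm <- function(spectrum, peptide, params = searchParams()) {
  pk <- peaks(spectrum)
  if (nrow(pk) == 0L) return(0)
  frag <- theoreticalFragments(peptide)
  m <- .matchedCount(frag, pk[, 1L], params@fragmentTolDa)
  .hypergeomScore(m, length(frag), nrow(pk),
                  max(pk[, 1L]) - min(pk[, 1L]), params@fragmentTolDa)
}

## unspecific digest of a Proteome side into unique substrings with first
## occurrence coordinates; returns data.frame(peptide, accession, start, mass)
.digestProteome <- function(proteome, lenRange) {
  seqs <- as.character(proteome@seqs)
  accs <- names(proteome@seqs)
  out <- vector("list", length(seqs) * (lenRange[2L] - lenRange[1L] + 1L))
  k <- 0L
  for (j in seq_along(seqs)) {
    s <- seqs[j]
    w <- nchar(s)
    chars <- strsplit(s, "")[[1L]]
    cum <- c(0, cumsum(AA_MONO_MASS[chars]))
    for (L in seq.int(lenRange[1L], lenRange[2L])) {
      if (w < L) next
      starts <- seq_len(w - L + 1L)
      k <- k + 1L
      out[[k]] <- data.frame(
        peptide = substring(s, starts, starts + L - 1L),
        accession = accs[j], start = starts - 1L,
        mass = cum[starts + L] - cum[starts] + WATER_MASS,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out[seq_len(k)])
  if (is.null(res)) return(data.frame(peptide = character(),
                                      accession = character(),
                                      start = integer(), mass = numeric()))
  res[!duplicated(res$peptide), , drop = FALSE]
}

## combined target proteome of a search database
.searchTargets <- function(db) {
  if (is(db, "TargetDatabase")) {
    ref <- referenceProteome(db)
    seqs <- c(proteinSequences(ref),
              setNames(as.character(splicedEntries(db)),
                       names(splicedEntries(db))))
    Proteome(seqs, ilCollapsed = isIlCollapsed(ref))
  } else if (is(db, "Proteome")) db
  else stop("'db' must be a TargetDatabase or Proteome")
}

#' Search spectra against a target database
#'
#' Concatenated target-decoy search with the stand-in engine: the target
#' database (reference plus in-silico spliced entries) and its whole-protein
#' reversed decoy are digested into unspecific substrings within the peptide
#' length range; candidates whose mass matches the precursor within the ppm
#' tolerance are scored with [scorePsm()], and the best-scoring candidate per
#' spectrum is retained (PSMs with no matched fragment are not reported).
#' Ties are broken target-over-decoy, then by lexicographic peptide, then by
#' first accession. Target PSMs are annotated with their splice category
#' against the reference portion of the database.
#'
#' @param spectra List of \linkS4class{Spectrum}.
#' @param db A \linkS4class{TargetDatabase} or plain \linkS4class{Proteome}.
#' @param params A \linkS4class{SearchParams}.
#' @param mapper A \linkS4class{MapperParams} for category assignment.
#' @return data.frame with one row per assigned spectrum: \code{spectrum_id},
#'   \code{peptide}, \code{score}, \code{is_decoy}, \code{accession},
#'   \code{assigned_category}, \code{n_matched}, \code{n_theoretical}.
#' @export
searchSpectra <- function(spectra, db, params = searchParams(),
                          mapper = mapperParams()) {
  targets <- .searchTargets(db)
  if (length(targets) == 0L) stop("empty search database")
  decoys <- makeDecoy(targets)
  poolT <- .digestProteome(targets, params@peptideLenRange)
  poolD <- .digestProteome(decoys, params@peptideLenRange)
  poolT$is_decoy <- FALSE
  poolD$is_decoy <- TRUE
  pool <- rbind(poolT, poolD)
  ord <- order(pool$mass)
  pool <- pool[ord, , drop = FALSE]
  masses <- pool$mass

  refIndex <- buildIndex(if (is(db, "TargetDatabase"))
    referenceProteome(db) else db)

  fragCache <- new.env(parent = emptyenv())
  getFrag <- function(p) {
    f <- fragCache[[p]]
    if (is.null(f)) f <- fragCache[[p]] <- theoreticalFragments(p)
    f
  }

  rows <- vector("list", length(spectra))
  for (si in seq_along(spectra)) {
    sp <- spectra[[si]]
    pk <- peaks(sp)
    if (nrow(pk) == 0L) next
    z <- precursorCharge(sp)
    M <- z * precursorMz(sp) - z * PROTON_MASS
    tol <- M * params@precursorTolPpm * 1e-6
    lo <- findInterval(M - tol, masses)
    hi <- findInterval(M + tol, masses)
    if (hi <= lo) next
    cand <- pool[(lo + 1L):hi, , drop = FALSE]
    mzRange <- max(pk[, 1L]) - min(pk[, 1L])
    nMatch <- integer(nrow(cand))
    score <- numeric(nrow(cand))
    for (ci in seq_len(nrow(cand))) {
      frag <- getFrag(cand$peptide[ci])
      m <- .matchedCount(frag, pk[, 1L], params@fragmentTolDa)
      nMatch[ci] <- m
      score[ci] <- .hypergeomScore(m, length(frag), nrow(pk), mzRange,
                                   params@fragmentTolDa)
    }
    keep <- nMatch > 0L
    if (!any(keep)) next
    cand <- cand[keep, , drop = FALSE]
    score <- score[keep]
    nMatch <- nMatch[keep]
    best <- order(-score, cand$is_decoy, cand$peptide, cand$accession)[1L]
    rows[[si]] <- data.frame(
      spectrum_id = spectrumId(sp), peptide = cand$peptide[best],
      score = score[best], is_decoy = cand$is_decoy[best],
      accession = cand$accession[best],
      assigned_category = NA_character_, n_matched = nMatch[best],
      n_theoretical = 2L * (nchar(cand$peptide[best]) - 1L),
      stringsAsFactors = FALSE)
  }
  psms <- do.call(rbind, rows[!vapply(rows, is.null, logical(1L))])
  if (is.null(psms))
    return(data.frame(spectrum_id = character(), peptide = character(),
                      score = numeric(), is_decoy = logical(),
                      accession = character(),
                      assigned_category = character(), n_matched = integer(),
                      n_theoretical = integer(), stringsAsFactors = FALSE))
  tgt <- !psms$is_decoy
  if (any(tgt)) {
    uniq <- unique(psms$peptide[tgt])
    catMap <- classifyPeptides(uniq, refIndex, mapper)
    psms$assigned_category[tgt] <- unname(catMap[psms$peptide[tgt]])
  }
  rownames(psms) <- NULL
  psms
}

#' Estimate the FDR at a score threshold
#'
#' Counts assigned target sequences (T) and decoy sequences (D) at or above
#' the threshold in a concatenated target-decoy search and estimates
#' \deqn{FDR = 100 \cdot 2D / (T + D)} in percent.
#'
#' @param psms PSM data.frame from [searchSpectra()] (or imported; needs
#'   \code{score} and \code{is_decoy}).
#' @param threshold Score threshold.
#' @return One-row data.frame: \code{threshold}, \code{n_target},
#'   \code{n_decoy}, \code{fdr_percent}, \code{empty} (TRUE when T + D = 0,
#'   in which case the FDR is reported as 0).
#' @export
estimateFdr <- function(psms, threshold) {
  keep <- psms$score >= threshold
  T <- sum(keep & !psms$is_decoy)
  D <- sum(keep & psms$is_decoy)
  data.frame(threshold = threshold, n_target = T, n_decoy = D,
             fdr_percent = if (T + D > 0L) 100 * 2 * D / (T + D) else 0,
             empty = (T + D) == 0L)
}

#' Sweep FDR estimates over a threshold schedule
#'
#' @param psms PSM data.frame.
#' @param thresholds Ascending numeric vector of score thresholds.
#' @return data.frame with one [estimateFdr()] row per threshold; target and
#'   decoy counts are non-increasing in the threshold.
#' @export
thresholdSweep <- function(psms, thresholds) {
  stopifnot(length(thresholds) > 0L, !is.unsorted(thresholds))
  do.call(rbind, lapply(thresholds, function(t) estimateFdr(psms, t)))
}

#' Default score threshold schedule
#'
#' A grid over the stand-in engine's -log10 tail-probability score, spanning
#' barely-significant matches to highly confident ones, analogous to the wide
#' engine-specific scoring schedules used for FDR-vs-PSM curves.
#'
#' @return Ascending numeric vector.
#' @export
defaultThresholds <- function() c(1, 1.5, 2, 2.5, 3, 4, 5, 7, 9, 12)

#' Pick the loosest threshold at a target FDR
#'
#' @param sweep A [thresholdSweep()] result.
#' @param targetFdrPercent Target estimated FDR in percent (e.g. 1).
#' @return One-row data.frame: \code{threshold}, \code{fdr_percent},
#'   \code{satisfied}. When no threshold attains the target the strictest
#'   threshold is returned with \code{satisfied = FALSE} and a warning.
#' @export
pickThresholdAtFdr <- function(sweep, targetFdrPercent) {
  stopifnot(nrow(sweep) > 0L)
  ok <- sweep$fdr_percent <= targetFdrPercent
  if (any(ok)) {
    i <- which(ok)[which.min(sweep$threshold[ok])]
    data.frame(threshold = sweep$threshold[i],
               fdr_percent = sweep$fdr_percent[i], satisfied = TRUE)
  } else {
    warning("no threshold attains ", targetFdrPercent,
            "% estimated FDR; returning the strictest")
    i <- which.max(sweep$threshold)
    data.frame(threshold = sweep$threshold[i],
               fdr_percent = sweep$fdr_percent[i], satisfied = FALSE)
  }
}
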
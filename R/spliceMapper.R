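## Classification of peptides against a proteome as non-spliced, cis-spliced
## (normal or reverse order), trans-spliced, or unexplainable, following the
## explanation hierarchy non-spliced > cis > trans.

.emptyExplanations <- function() {
  data.frame(category = character(), splitPoint = integer(),
             leftAccession = character(), leftStart = integer(),
             leftEnd = integer(), rightAccession = character(),
             rightStart = integer(), rightEnd = integer(),
             interveningLen = integer(), stringsAsFactors = FALSE)
}

#' Enumerate all reactant splits of a peptide
#'
#' Splits a candidate sequence into every ordered (prefix, suffix) pair of
#' splice reactants. A 9-mer with minimum reactant length 1 yields the eight
#' combinations with reactant lengths [1+8], [2+7], ..., [8+1].
#'
#' @param peptide A single peptide string.
#' @param minReactantLen Minimum reactant length (default 1).
#' @return data.frame with columns \code{splitPoint} (length of the left
#'   reactant), \code{left}, \code{right}. Zero rows if the peptide is shorter
#'   than twice the minimum reactant length.
#' @examples
#' enumerateSplits("ABCDEFGHK")   # 8 splits
#' @export
enumerateSplits <- function(peptide, minReactantLen = 1) {
  stopifnot(is.character(peptide), length(peptide) == 1L)
  n <- nchar(peptide)
  m <- as.integer(minReactantLen)
  if (n < 2L * m)
    return(data.frame(splitPoint = integer(), left = character(),
                      right = character(), stringsAsFactors = FALSE))
  s <- seq.int(m, n - m)
  data.frame(splitPoint = s,
             left = substring(peptide, 1L, s),
             right = substring(peptide, s + 1L, n),
             stringsAsFactors = FALSE)
}

.checkCollapseState <- function(peptide, index) {
  if (index@ilCollapsed && grepl("I", peptide, fixed = TRUE))
    stop("peptide '", peptide, "' contains isoleucine but the proteome is ",
         "I/L-collapsed; collapse the peptide first (collapseIL)")
}

## all (left occurrence, right occurrence) cis pairs within one protein.
## occL/occR: data.frames from lookupOccurrences. reverse = TRUE measures the
## intervening stretch from right-reactant end to left-reactant start
## (reverse-order splicing).
.cisPairs <- function(occL, occR, maxIntervening, allowOverlap,
                      reverse = FALSE) {
  common <- intersect(occL$entry, occR$entry)
  if (length(common) == 0L) return(NULL)
  out <- vector("list", length(common))
  for (k in seq_along(common)) {
    e <- common[k]
    L <- occL[occL$entry == e, , drop = FALSE]
    R <- occR[occR$entry == e, , drop = FALSE]
    ii <- rep(seq_len(nrow(L)), each = nrow(R))
    jj <- rep.int(seq_len(nrow(R)), nrow(L))
    gap <- if (reverse) L$start[ii] - R$end[jj] else R$start[jj] - L$end[ii]
    keep <- gap <= maxIntervening & (allowOverlap | gap >= 0L)
    if (!any(keep)) next
    out[[k]] <- data.frame(
      leftEntry = e, leftStart = L$start[ii][keep], leftEnd = L$end[ii][keep],
      rightEntry = e, rightStart = R$start[jj][keep],
      rightEnd = R$end[jj][keep], interveningLen = gap[keep],
      stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, logical(1L))]
  if (length(out) == 0L) NULL else do.call(rbind, out)
}

## TRUE iff some cross-entry (left, right) pair exists
.hasTransPair <- function(occL, occR) {
  if (nrow(occL) == 0L || nrow(occR) == 0L) return(FALSE)
  uL <- unique(occL$entry)
  uR <- unique(occR$entry)
  !(length(uL) == 1L && length(uR) == 1L && uL == uR)
}

## same-entry pairs with intervening beyond the cap, either orientation
## (only consulted when longCisAsTrans is set)
.hasLongCisPair <- function(occL, occR, maxIntervening) {
  common <- intersect(occL$entry, occR$entry)
  for (e in common) {
    L <- occL[occL$entry == e, , drop = FALSE]
    R <- occR[occR$entry == e, , drop = FALSE]
    for (i in seq_len(nrow(L))) {
      if (any(R$start - L$end[i] > maxIntervening) ||
          any(L$start[i] - R$end > maxIntervening))
        return(TRUE)
    }
  }
  FALSE
}

#' Enumerate all splice explanations of a peptide
#'
#' Complete enumeration over all reactant splits and all occurrence pairs:
#' whole-peptide occurrences give non-spliced explanations; same-protein
#' reactant pairs whose intervening stretch is within the cap give cis
#' explanations (normal order when the left reactant lies upstream in the
#' protein, reverse order otherwise); different-protein pairs give trans
#' explanations.
#'
#' @param peptide A single peptide string (same I/L collapse state as the
#'   index).
#' @param index A \linkS4class{SubstringIndex}.
#' @param params A \linkS4class{MapperParams}.
#' @return data.frame with one row per explanation: \code{category}
#'   (\code{NONSPLICED}, \code{CIS_NORMAL}, \code{CIS_REVERSE},
#'   \code{TRANS}), \code{splitPoint}, left/right occurrence coordinates
#'   (0-based half-open) and \code{interveningLen} (cis only). Rows are in
#'   deterministic (category priority, split point, entry order, start) order.
#' @export
findExplanations <- function(peptide, index, params = mapperParams()) {
  stopifnot(is(index, "SubstringIndex"), is(params, "MapperParams"),
            is.character(peptide), length(peptide) == 1L, nchar(peptide) > 0L)
  .checkCollapseState(peptide, index)

  acc <- index@accessions
  rows <- list()

  full <- lookupOccurrences(index, peptide)
  if (nrow(full) > 0L)
    rows$non <- data.frame(
      category = "NONSPLICED", splitPoint = NA_integer_,
      leftAccession = full$accession, leftStart = full$start,
      leftEnd = full$end, rightAccession = NA_character_,
      rightStart = NA_integer_, rightEnd = NA_integer_,
      interveningLen = NA_integer_, leftEntry = full$entry,
      rightEntry = NA_integer_, stringsAsFactors = FALSE)

  splits <- enumerateSplits(peptide, params@minReactantLen)
  occCache <- new.env(parent = emptyenv())
  getOcc <- function(s) {
    if (is.null(occCache[[s]])) occCache[[s]] <- lookupOccurrences(index, s)
    occCache[[s]]
  }
  for (i in seq_len(nrow(splits))) {
    occL <- getOcc(splits$left[i])
    occR <- getOcc(splits$right[i])
    if (nrow(occL) == 0L || nrow(occR) == 0L) next
    sp <- splits$splitPoint[i]
    for (rev in c(FALSE, TRUE)) {
      cp <- .cisPairs(occL, occR, params@maxIntervening,
                      params@allowOverlap, reverse = rev)
      if (!is.null(cp))
        rows[[length(rows) + 1L]] <- data.frame(
          category = if (rev) "CIS_REVERSE" else "CIS_NORMAL",
          splitPoint = sp, leftAccession = acc[cp$leftEntry],
          leftStart = cp$leftStart, leftEnd = cp$leftEnd,
          rightAccession = acc[cp$rightEntry], rightStart = cp$rightStart,
          rightEnd = cp$rightEnd, interveningLen = cp$interveningLen,
          leftEntry = cp$leftEntry, rightEntry = cp$rightEntry,
          stringsAsFactors = FALSE)
    }
    ## trans: all cross-entry pairs
    ii <- rep(seq_len(nrow(occL)), each = nrow(occR))
    jj <- rep.int(seq_len(nrow(occR)), nrow(occL))
    cross <- occL$entry[ii] != occR$entry[jj]
    if (isTRUE(params@longCisAsTrans)) {
      gapN <- occR$start[jj] - occL$end[ii]
      gapR <- occL$start[ii] - occR$end[jj]
      long <- !cross & (gapN > params@maxIntervening |
                        gapR > params@maxIntervening)
      cross <- cross | long
    }
    if (any(cross))
      rows[[length(rows) + 1L]] <- data.frame(
        category = "TRANS", splitPoint = sp,
        leftAccession = occL$accession[ii][cross],
        leftStart = occL$start[ii][cross], leftEnd = occL$end[ii][cross],
        rightAccession = occR$accession[jj][cross],
        rightStart = occR$start[jj][cross], rightEnd = occR$end[jj][cross],
        interveningLen = NA_integer_, leftEntry = occL$entry[ii][cross],
        rightEntry = occR$entry[jj][cross], stringsAsFactors = FALSE)
  }

  if (length(rows) == 0L) return(.emptyExplanations())
  out <- do.call(rbind, rows)
  pr <- CATEGORY_PRIORITY[sub("_.*$", "", sub("CIS_.*", "CIS", out$category))]
  ord <- order(-pr, out$splitPoint, out$leftEntry, out$leftStart,
               out$rightEntry, out$rightStart, method = "radix",
               na.last = FALSE)
  out <- out[ord, setdiff(names(out), c("leftEntry", "rightEntry")),
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify a peptide under the explanation hierarchy
#'
#' Applies the hierarchy that prefers non-spliced over any spliced explanation
#' and cis- over trans-spliced explanations: the winning category is the
#' highest-priority one with at least one explanation, and only explanations
#' of that category are reported. Normal- and reverse-order cis explanations
#' are both reported under category \code{"CIS"}.
#'
#' @inheritParams findExplanations
#' @return A \linkS4class{Classification} with category one of
#'   \code{"NONSPLICED"}, \code{"CIS"}, \code{"TRANS"}, \code{"NONE"}.
#' @examples
#' idx <- buildIndex(Proteome(c(P1 = "MKLLPETGAL")))
#' category(classifyPeptide("LPETG", idx))   # NONSPLICED
#' category(classifyPeptide("MKGAL", idx))   # CIS
#' @export
classifyPeptide <- function(peptide, index, params = mapperParams()) {
  ex <- findExplanations(peptide, index, params)
  base <- sub("CIS_.*", "CIS", ex$category)
  win <- if (nrow(ex) == 0L) "NONE" else
    names(CATEGORY_PRIORITY)[match(max(CATEGORY_PRIORITY[base]),
                                   CATEGORY_PRIORITY)]
  keep <- if (win == "NONE") .emptyExplanations() else
    ex[base == win, , drop = FALSE]
  rownames(keep) <- NULL
  new("Classification", peptide = peptide, category = win,
      explanations = keep)
}

#' Classify many peptides (categories only)
#'
#' A fast vector interface over the same hierarchy as [classifyPeptide()],
#' skipping explanation enumeration: for each peptide only the existence of a
#' non-spliced, cis or trans explanation is tested, with short-circuiting.
#'
#' @param peptides Character vector of peptides.
#' @inheritParams findExplanations
#' @return Character vector of categories, one per peptide.
#' @export
classifyPeptides <- function(peptides, index, params = mapperParams()) {
  vapply(peptides, .classifyCategory, character(1L),
         index = index, params = params, USE.NAMES = TRUE)
}

## category-only fast path; identical verdicts to classifyPeptide()
.classifyCategory <- function(peptide, index, params = mapperParams()) {
  .checkCollapseState(peptide, index)
  if (length(.indexPositions(index, peptide)) > 0L) return("NONSPLICED")
  splits <- enumerateSplits(peptide, params@minReactantLen)
  if (nrow(splits) == 0L) return("NONE")
  occs <- lapply(seq_len(nrow(splits)), function(i) {
    L <- lookupOccurrences(index, splits$left[i])
    if (nrow(L) == 0L) return(NULL)
    R <- lookupOccurrences(index, splits$right[i])
    if (nrow(R) == 0L) return(NULL)
    list(L = L, R = R)
  })
  for (o in occs) {
    if (is.null(o)) next
    if (!is.null(.cisPairs(o$L, o$R, params@maxIntervening,
                           params@allowOverlap, reverse = FALSE)) ||
        !is.null(.cisPairs(o$L, o$R, params@maxIntervening,
                           params@allowOverlap, reverse = TRUE)))
      return("CIS")
  }
  for (o in occs) {
    if (is.null(o)) next
    if (.hasTransPair(o$L, o$R)) return("TRANS")
    if (isTRUE(params@longCisAsTrans) &&
        .hasLongCisPair(o$L, o$R, params@maxIntervening)) return("TRANS")
  }
  "NONE"
}
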
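## AP and MBS target-database generation from de novo candidate tables, and
## target-database feature computation (candidate truth ratios, sizes).

.lcsValues <- function(lcs) {
  lapply(strsplit(lcs, ";", fixed = TRUE), as.numeric)
}

#' Compute the AP ALC cutoff
#'
#' The cutoff is derived from the ALC distribution of non-spliced peptides
#' identified both by the database search (at high confidence) and by de novo
#' sequencing: rank-1 de novo candidates whose sequence agrees (after I/L
#' collapse) with the confident database assignment of the same spectrum. The
#' returned value is a lower quantile (default 5%) of the agreeing ALCs.
#'
#' @param denovo De novo candidate data.frame (\code{spectrum_id},
#'   \code{rank}, \code{sequence}, \code{alc}, \code{lcs}).
#' @param confidentNonspliced Named character vector: spectrum_id ->
#'   confidently assigned non-spliced sequence.
#' @param quantile Lower quantile of the agreeing ALC distribution
#'   (default 0.05).
#' @return Numeric ALC cutoff.
#' @export
computeAlcCutoff <- function(denovo, confidentNonspliced, quantile = 0.05) {
  r1 <- denovo[denovo$rank == 1L &
                 denovo$spectrum_id %in% names(confidentNonspliced), ,
               drop = FALSE]
  agree <- collapseIL(r1$sequence) ==
    collapseIL(unname(confidentNonspliced[r1$spectrum_id]))
  alcs <- r1$alc[agree]
  if (length(alcs) == 0L)
    stop("no spectrum has an agreeing rank-1 de novo and confident database ",
         "sequence; supply an ALC cutoff manually")
  unname(stats::quantile(alcs, probs = quantile, type = 1L))
}

## classify every unique candidate sequence once
.candidateCategories <- function(sequences, index, params) {
  uniq <- unique(sequences)
  classifyPeptides(uniq, index, params)
}

#' AP candidate selection
#'
#' Per spectrum: candidates at or below the ALC cutoff are dropped (the
#' filter is strict, ALC must exceed the cutoff); if any surviving candidate
#' maps as non-spliced the whole spectrum is discarded; otherwise the single
#' highest-ALC cis-spliced candidate is retained; failing that, the single
#' highest-ALC trans-spliced candidate; otherwise nothing. At most one
#' candidate is retained per spectrum.
#'
#' @param denovo De novo candidate data.frame.
#' @param index \linkS4class{SubstringIndex} over the reference database.
#' @param alcCutoff ALC cutoff (see [computeAlcCutoff()]).
#' @param params \linkS4class{MapperParams}.
#' @param excludeSpectra Spectrum ids to skip (e.g. spectra already assigned
#'   as confident non-spliced peptides in the first-pass search).
#' @return data.frame of retained candidates with a \code{category} column.
#' @export
apSelectCandidates <- function(denovo, index, alcCutoff,
                               params = mapperParams(),
                               excludeSpectra = character()) {
  dn <- denovo[!(denovo$spectrum_id %in% excludeSpectra) &
                 denovo$alc > alcCutoff, , drop = FALSE]
  if (nrow(dn) == 0L) return(cbind(dn, category = character(0L)))
  cats <- .candidateCategories(dn$sequence, index, params)
  dn$category <- unname(cats[dn$sequence])
  keep <- lapply(split(dn, dn$spectrum_id), function(g) {
    if (any(g$category == "NONSPLICED")) return(NULL)
    for (want in c("CIS", "TRANS")) {
      h <- g[g$category == want, , drop = FALSE]
      if (nrow(h) > 0L)
        return(h[order(-h$alc, h$rank, h$sequence)[1L], , drop = FALSE])
    }
    NULL
  })
  keep <- keep[!vapply(keep, is.null, logical(1L))]
  if (length(keep) == 0L)
    return(dn[0L, , drop = FALSE])
  out <- do.call(rbind, keep)
  out <- out[order(out$spectrum_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' MBS candidate selection
#'
#' Retains every candidate whose per-residue local confidence scores are all
#' at least \code{lcsMin} (default 80) and that maps as cis-spliced (with the
#' intervening cap of \code{params}, default 25 residues). Candidates that
#' map as non-spliced are never retained; several candidates per spectrum may
#' be.
#'
#' @inheritParams apSelectCandidates
#' @param lcsMin Minimum per-residue LCS (default 80).
#' @return data.frame of retained candidates with a \code{category} column.
#' @export
mbsSelectCandidates <- function(denovo, index, lcsMin = 80,
                                params = mapperParams(),
                                excludeSpectra = character()) {
  dn <- denovo[!(denovo$spectrum_id %in% excludeSpectra), , drop = FALSE]
  minLcs <- vapply(.lcsValues(dn$lcs), function(v)
    if (length(v)) min(v) else -Inf, numeric(1L))
  dn <- dn[minLcs >= lcsMin, , drop = FALSE]
  if (nrow(dn) == 0L) return(cbind(dn, category = character(0L)))
  cats <- .candidateCategories(dn$sequence, index, params)
  dn$category <- unname(cats[dn$sequence])
  out <- dn[dn$category == "CIS", , drop = FALSE]
  out <- out[order(out$spectrum_id, out$rank), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build a spliced-peptide target database
#'
#' Appends the retained candidate sequences to the reference proteome. In AP
#' mode candidates are concatenated into in-silico proteins of
#' \code{chunkSize} candidates each; in MBS mode each candidate becomes its
#' own entry. Entry order follows input order; accessions carry the
#' \code{"SPLICED_"} prefix.
#'
#' @param retained Retained candidate data.frame (from
#'   [apSelectCandidates()] or [mbsSelectCandidates()]), or a character
#'   vector of sequences.
#' @param reference The reference \linkS4class{Proteome}.
#' @param mode \code{"AP"} or \code{"MBS"}.
#' @param chunkSize Candidates per in-silico protein in AP mode (default 25).
#' @return A \linkS4class{TargetDatabase}.
#' @export
buildTargetDb <- function(retained, reference, mode = c("AP", "MBS"),
                          chunkSize = 25) {
  mode <- match.arg(mode)
  stopifnot(is(reference, "Proteome"))
  if (is.character(retained))
    retained <- data.frame(spectrum_id = NA_character_, sequence = retained,
                           stringsAsFactors = FALSE)
  seqs <- retained$sequence
  if (length(seqs) == 0L) {
    return(new("TargetDatabase", reference = reference,
               splicedEntries = Biostrings::AAStringSet(),
               provenance = cbind(retained,
                                  entry = character(0L)), mode = mode))
  }
  if (mode == "AP") {
    grp <- ceiling(seq_along(seqs) / chunkSize)
    entries <- vapply(split(seqs, grp), paste, character(1L), collapse = "")
    names(entries) <- sprintf("%sAP_%04d", SPLICED_TAG,
                              seq_along(unique(grp)))
    entryOf <- names(entries)[grp]
  } else {
    entries <- setNames(seqs, sprintf("%s%04d", SPLICED_TAG,
                                      seq_along(seqs)))
    entryOf <- names(entries)
  }
  prov <- retained
  prov$entry <- entryOf
  rownames(prov) <- NULL
  new("TargetDatabase", reference = reference,
      splicedEntries = Biostrings::AAStringSet(entries),
      provenance = prov, mode = mode)
}

#' Target database truth features
#'
#' Computes, against a ground-truth bundle, the number of unique candidate
#' sequences in the database, how many of them are true cis-spliced target
#' peptides, the total number of true cis-spliced peptides, and the two
#' ratios: true candidates over all candidates (the database's precision
#' potential) and true candidates over all true cis peptides (its recall
#' potential).
#'
#' @param db A \linkS4class{TargetDatabase}.
#' @param truth A \linkS4class{GroundTruthBundle}.
#' @return One-row data.frame: \code{n_candidates}, \code{n_true_candidates},
#'   \code{n_true_total}, \code{precision_potential},
#'   \code{recall_potential}.
#' @export
targetDbFeatures <- function(db, truth) {
  stopifnot(is(db, "TargetDatabase"), is(truth, "GroundTruthBundle"))
  cand <- unique(collapseIL(provenance(db)$sequence))
  labels <- categoryLabels(truth)
  trueCis <- collapseIL(names(labels)[labels == "CIS"])
  nC <- length(cand)
  nTC <- sum(cand %in% trueCis)
  nTT <- length(trueCis)
  data.frame(n_candidates = nC, n_true_candidates = nTC, n_true_total = nTT,
             precision_potential = if (nC > 0L) nTC / nC else NA_real_,
             recall_potential = if (nTT > 0L) nTC / nTT else NA_real_)
}
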
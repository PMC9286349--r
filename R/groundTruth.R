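## Construction of ground-truth reference databases: every target peptide is
## made identifiable only as its assigned category (non-spliced, cis-spliced,
## or trapping/unidentifiable) by eliding it from the database and re-planting
## it in the prescribed form, with verification after every plant.

.randomResidues <- function(n, alphabet) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

.gtAlphabet <- function(collapsed) {
  if (collapsed) AA_ALPHABET19 else AA_ALPHABET20
}

#' Partition target peptides into the three categories
#'
#' Randomly assigns target peptides to the non-spliced, cis-spliced and
#' trapping categories by a seeded shuffle, in the proportions given by
#' \code{categoryWeights} (equal thirds by default, so list sizes differ by at
#' most one).
#'
#' @param peptides Character vector of unique target peptides.
#' @param params A \linkS4class{GroundTruthParams}.
#' @return Named list of three character vectors: \code{NONSPLICED},
#'   \code{CIS}, \code{TRAPPING}.
#' @export
partitionTargets <- function(peptides, params = groundTruthParams()) {
  stopifnot(is(params, "GroundTruthParams"))
  if (anyDuplicated(peptides))
    stop("duplicate target peptide: ", peptides[duplicated(peptides)][1L])
  if (!is.na(params@seed)) set.seed(params@seed)
  n <- length(peptides)
  shuffled <- if (n > 0L) sample(peptides) else character()
  ## largest-remainder apportionment of n over the three weights
  w <- params@categoryWeights
  base <- floor(w * n)
  rem <- n - sum(base)
  if (rem > 0L) {
    extra <- order(w * n - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1L
  }
  splits <- cumsum(base)
  list(NONSPLICED = shuffled[seq_len(base[1L])],
       CIS = shuffled[seq_len(base[2L]) + splits[1L]],
       TRAPPING = shuffled[seq_len(base[3L]) + splits[2L]])
}

#' Elide target peptides from a reference database
#'
#' Replaces every substring of any database sequence identical to a target
#' peptide by a randomly sampled residue string of the same length, redrawing
#' until no target peptide occurs anywhere (replacements can themselves create
#' target occurrences, and overlapping target occurrences interact).
#' Sequence lengths are always preserved.
#'
#' @param proteome A \linkS4class{Proteome} (I/L-collapsed when the targets
#'   are).
#' @param peptides Character vector of target peptides.
#' @param params A \linkS4class{GroundTruthParams}; \code{maxRetries} bounds
#'   the redraw passes.
#' @return A \linkS4class{Proteome} free of all target peptides.
#' @export
elideTargets <- function(proteome, peptides, params = groundTruthParams()) {
  stopifnot(is(proteome, "Proteome"))
  if (!is.na(params@seed)) set.seed(params@seed)
  if (proteome@ilCollapsed && any(grepl("I", peptides, fixed = TRUE)))
    stop("target peptides contain isoleucine but the proteome is I/L-collapsed")
  seqs <- as.character(proteome@seqs)
  alpha <- .gtAlphabet(proteome@ilCollapsed)
  offender <- NULL
  for (pass in seq_len(params@maxRetries)) {
    dirty <- FALSE
    for (t in peptides) {
      hit <- grep(t, seqs, fixed = TRUE)
      for (j in hit) {
        starts <- .entryStarts(seqs[j], t)
        for (s0 in starts) {
          substr(seqs[j], s0 + 1L, s0 + nchar(t)) <-
            .randomResidues(nchar(t), alpha)
        }
        dirty <- TRUE
        offender <- t
      }
    }
    if (!dirty)
      return(Proteome(setNames(seqs, names(proteome@seqs)),
                      ilCollapsed = proteome@ilCollapsed))
  }
  stop("could not elide target peptide '", offender, "' within ",
       params@maxRetries, " redraw passes")
}

#' Plant one target peptide into a proteome
#'
#' Appends a target to the database in the form dictated by its category:
#' \describe{
#'   \item{NONSPLICED}{the whole peptide is appended to the N- or C-terminus
#'     of one randomly sampled protein;}
#'   \item{CIS}{a splice site is sampled within the peptide, and
#'     \code{reactant1 + intervening + reactant2} (intervening length uniform
#'     on 1..\code{maxIntervening}, residues uniform) is appended as one
#'     contiguous block to one terminus of one protein;}
#'   \item{TRAPPING}{the two reactants are appended to termini of two
#'     distinct proteins, so the peptide is explainable only as
#'     trans-spliced.}
#' }
#'
#' @param proteome A \linkS4class{Proteome}.
#' @param peptide A single target peptide.
#' @param category \code{"NONSPLICED"}, \code{"CIS"} or \code{"TRAPPING"}.
#' @param params A \linkS4class{GroundTruthParams}.
#' @return List with elements \code{proteome} (modified database) and
#'   \code{record} (one-row data.frame: peptide, category, host accessions,
#'   termini, split point, intervening sequence).
#' @export
plantTarget <- function(proteome, peptide, category,
                        params = groundTruthParams()) {
  stopifnot(is(proteome, "Proteome"), is.character(peptide),
            length(peptide) == 1L)
  category <- match.arg(category, c("NONSPLICED", "CIS", "TRAPPING"))
  if (!is.na(params@seed)) set.seed(params@seed)
  if (category == "TRAPPING" && length(proteome) < 2L)
    stop("trapping plants need at least two database entries")
  seqs <- as.character(proteome@seqs)
  n <- nchar(peptide)
  alpha <- .gtAlphabet(proteome@ilCollapsed)

  appendAt <- function(seq, block, terminus) {
    if (terminus == "C") paste0(seq, block) else paste0(block, seq)
  }

  if (category == "NONSPLICED") {
    host <- sample(length(seqs), 1L)
    term <- sample(c("N", "C"), 1L)
    seqs[host] <- appendAt(seqs[host], peptide, term)
    rec <- data.frame(peptide = peptide, category = category,
                      host1 = names(proteome@seqs)[host],
                      host2 = NA_character_, terminus1 = term,
                      terminus2 = NA_character_, splitPoint = NA_integer_,
                      interveningSeq = NA_character_,
                      stringsAsFactors = FALSE)
  } else {
    sp <- sample(n - 1L, 1L)
    left <- substr(peptide, 1L, sp)
    right <- substr(peptide, sp + 1L, n)
    if (category == "CIS") {
      ivLen <- sample(params@maxIntervening, 1L)
      iv <- .randomResidues(ivLen, alpha)
      host <- sample(length(seqs), 1L)
      term <- sample(c("N", "C"), 1L)
      seqs[host] <- appendAt(seqs[host], paste0(left, iv, right), term)
      rec <- data.frame(peptide = peptide, category = category,
                        host1 = names(proteome@seqs)[host],
                        host2 = NA_character_, terminus1 = term,
                        terminus2 = NA_character_, splitPoint = sp,
                        interveningSeq = iv, stringsAsFactors = FALSE)
    } else {
      hosts <- sample(length(seqs), 2L)
      terms <- sample(c("N", "C"), 2L, replace = TRUE)
      seqs[hosts[1L]] <- appendAt(seqs[hosts[1L]], left, terms[1L])
      seqs[hosts[2L]] <- appendAt(seqs[hosts[2L]], right, terms[2L])
      rec <- data.frame(peptide = peptide, category = category,
                        host1 = names(proteome@seqs)[hosts[1L]],
                        host2 = names(proteome@seqs)[hosts[2L]],
                        terminus1 = terms[1L], terminus2 = terms[2L],
                        splitPoint = sp, interveningSeq = NA_character_,
                        stringsAsFactors = FALSE)
    }
  }
  list(proteome = Proteome(setNames(seqs, names(proteome@seqs)),
                           ilCollapsed = proteome@ilCollapsed),
       record = rec)
}

## ---- incremental verification machinery ----------------------------------

## per-target screen k-mers: any cis or non-spliced occurrence of target t in
## a protein implies some k_t-mer of t occurs there (one reactant always has
## length >= ceiling(n/2) >= k_t), so a k-mer screen is a sound prefilter.
.screenK <- function(n) min(4L, as.integer(ceiling(n / 2)))

.kmers <- function(x, k) {
  n <- nchar(x)
  if (n < k) return(character())
  unique(substring(x, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L))
}

## does `t` have a cis explanation fully inside the single sequence `seqChar`?
.hasCisWithin <- function(seqChar, t, maxIntervening) {
  n <- nchar(t)
  for (sp in seq_len(n - 1L)) {
    left <- substr(t, 1L, sp)
    right <- substr(t, sp + 1L, n)
    ## search the longer reactant first: almost always absent, cheap bail-out
    if (sp >= n - sp) {
      a <- .entryStarts(seqChar, left)
      if (length(a) == 0L) next
      b <- .entryStarts(seqChar, right)
      if (length(b) == 0L) next
    } else {
      b <- .entryStarts(seqChar, right)
      if (length(b) == 0L) next
      a <- .entryStarts(seqChar, left)
      if (length(a) == 0L) next
    }
    aEnd <- a + sp
    bEnd <- b + (n - sp)
    for (i in seq_along(a)) {
      gapN <- b - aEnd[i]
      gapR <- a[i] - bEnd
      if (any(gapN >= 0L & gapN <= maxIntervening) ||
          any(gapR >= 0L & gapR <= maxIntervening)) return(TRUE)
    }
  }
  FALSE
}

## Elision removes whole-target occurrences, but when two targets overlap in
## the source database, eliding one leaves a long partial remnant of the
## other in place; such a remnant is a valid splice reactant and can, with
## a chance occurrence of the short complementary reactant nearby, give a
## target an explanation above its intended category before anything is
## planted. This pass scrambles the offending reactant occurrences (and any
## re-created whole-target occurrence) until the database is clean.
.repairElision <- function(seqs, accs, targets, ceilPr, params) {
  alpha <- AA_ALPHABET19
  mp <- mapperParams(maxIntervening = params@maxIntervening)
  for (pass in seq_len(params@maxRetries)) {
    dirty <- FALSE
    idx <- buildIndex(Proteome(setNames(seqs, accs), ilCollapsed = TRUE))
    for (i in seq_along(targets)) {
      t <- targets[i]
      ## whole-target occurrences (possibly re-created by a scramble)
      occ <- lookupOccurrences(idx, t)
      if (nrow(occ) > 0L) {
        for (r in seq_len(nrow(occ))) {
          substr(seqs[occ$entry[r]], occ$start[r] + 1L, occ$end[r]) <-
            .randomResidues(nchar(t), alpha)
        }
        dirty <- TRUE
        idx <- buildIndex(Proteome(setNames(seqs, accs),
                                   ilCollapsed = TRUE))
      }
      if (ceilPr[i] >= 2L) next
      cl <- classifyPeptide(t, idx, mp)
      if (category(cl) == "CIS") {
        ## scramble the longer reactant of the first offending explanation
        ex <- explanations(cl)[1L, ]
        lenL <- ex$leftEnd - ex$leftStart
        lenR <- ex$rightEnd - ex$rightStart
        if (lenL >= lenR) {
          e <- match(ex$leftAccession, accs)
          substr(seqs[e], ex$leftStart + 1L, ex$leftEnd) <-
            .randomResidues(lenL, alpha)
        } else {
          e <- match(ex$rightAccession, accs)
          substr(seqs[e], ex$rightStart + 1L, ex$rightEnd) <-
            .randomResidues(lenR, alpha)
        }
        dirty <- TRUE
        idx <- buildIndex(Proteome(setNames(seqs, accs),
                                   ilCollapsed = TRUE))
      }
    }
    if (!dirty) return(seqs)
  }
  stop("could not make the elided database conflict-free within ",
       params@maxRetries, " repair passes")
}

#' Build a constructed ground-truth database
#'
#' Runs the full construction pipeline: I/L collapse, random partition of the
#' targets into the three categories, elision of every target from the
#' reference, and sequential planting of each target with verification after
#' every plant. A plant that would let any target (planted or pending) be
#' assigned a category above its intended one is rolled back and re-sampled
#' with a fresh host, terminus, split site and intervening sequence, up to
#' \code{maxRetries} times. The returned bundle always passes
#' [verifyCategories()].
#'
#' Because planting only appends residues, the observed category of a target
#' can only move up the hierarchy as construction proceeds; verification
#' therefore only needs to test, after each plant, that no target gained an
#' explanation above its intended category inside the one or two proteins
#' that were just modified.
#'
#' @param proteome The reference \linkS4class{Proteome} (collapsed internally
#'   if needed).
#' @param peptides Character vector of target peptides (unique after I/L
#'   collapse).
#' @param params A \linkS4class{GroundTruthParams}.
#' @return A \linkS4class{GroundTruthBundle}.
#' @export
buildGroundTruth <- function(proteome, peptides,
                             params = groundTruthParams()) {
  stopifnot(is(proteome, "Proteome"))
  if (!is.na(params@seed)) set.seed(params@seed)
  innerParams <- params
  innerParams@seed <- NA_integer_

  if (!proteome@ilCollapsed) proteome <- collapseIL(proteome)
  peptides <- collapseIL(peptides)
  if (anyDuplicated(peptides))
    stop("target peptides are not unique after I/L collapse: ",
         peptides[duplicated(peptides)][1L])

  part <- partitionTargets(peptides, innerParams)
  if (length(peptides) == 0L) {
    return(new("GroundTruthBundle", constructedDb = proteome,
               labels = setNames(character(), character()),
               plants = data.frame(),
               verification = data.frame(peptide = character(),
                                         intended = character(),
                                         observed = character(),
                                         ok = logical())))
  }
  proteome <- elideTargets(proteome, peptides, innerParams)

  targets <- c(part$NONSPLICED, part$CIS, part$TRAPPING)
  intended <- setNames(rep(c("NONSPLICED", "CIS", "TRAPPING"),
                           lengths(part)), targets)
  ## ceiling priority a target may reach without violating its intent
  ceilPr <- ifelse(intended == "NONSPLICED", 3L,
                   ifelse(intended == "CIS", 2L, 1L))
  screenKs <- vapply(targets, function(t) .screenK(nchar(t)), integer(1L))
  screenSets <- lapply(seq_along(targets),
                       function(i) .kmers(targets[i], screenKs[i]))

  seqs <- as.character(proteome@seqs)
  accs <- names(proteome@seqs)
  seqs <- .repairElision(seqs, accs, targets, ceilPr, params)
  plants <- vector("list", length(targets))

  ## check = can target i now be assigned above its intended category using
  ## material inside modified entries `mod`?
  violatesIn <- function(mod) {
    for (m in mod) {
      sq <- seqs[m]
      ks <- sort(unique(screenKs))
      mset <- lapply(ks, function(k) .kmers(sq, k))
      names(mset) <- as.character(ks)
      for (i in seq_along(targets)) {
        if (ceilPr[i] >= 3L) next            # non-spliced intent: nothing above
        if (!any(screenSets[[i]] %in% mset[[as.character(screenKs[i])]]))
          next
        t <- targets[i]
        if (length(.entryStarts(sq, t)) > 0L) return(t)   # non-spliced gained
        if (ceilPr[i] < 2L &&
            .hasCisWithin(sq, t, params@maxIntervening)) return(t)
      }
    }
    NULL
  }

  for (i in seq_along(targets)) {
    t <- targets[i]
    cat_i <- intended[[t]]
    planted <- FALSE
    for (attempt in seq_len(params@maxRetries)) {
      snapshot <- seqs
      pl <- plantTarget(Proteome(setNames(seqs, accs),
                                 ilCollapsed = TRUE),
                        t, cat_i, innerParams)
      seqs <- as.character(pl$proteome@seqs)
      mod <- match(stats::na.omit(c(pl$record$host1, pl$record$host2)), accs)
      bad <- violatesIn(mod)
      if (is.null(bad)) {
        plants[[i]] <- pl$record
        planted <- TRUE
        break
      }
      seqs <- snapshot                       # roll back and re-sample
    }
    if (!planted)
      stop("could not plant target '", t, "' (", cat_i, ") without letting ",
           "another target change category, after ", params@maxRetries,
           " attempts")
  }

  db <- Proteome(setNames(seqs, accs), ilCollapsed = TRUE)
  bundle <- new("GroundTruthBundle", constructedDb = db, labels = intended,
                plants = do.call(rbind, plants),
                verification = data.frame())
  bundle@verification <- verifyCategories(
    bundle, mapperParams(maxIntervening = params@maxIntervening))
  if (!all(bundle@verification$ok)) {
    bad <- bundle@verification[!bundle@verification$ok, ]
    stop("ground-truth verification failed for ", nrow(bad), " target(s), ",
         "first: ", bad$peptide[1L], " intended ", bad$intended[1L],
         " observed ", bad$observed[1L])
  }
  bundle
}

#' Verify intended vs observed categories of a bundle
#'
#' Classifies every labelled target peptide against the constructed database
#' and compares the observed category with the intended one. Trapping targets
#' pass when observed as \code{TRANS} or \code{NONE} (unidentifiable under a
#' non-spliced/cis search strategy).
#'
#' @param bundle A \linkS4class{GroundTruthBundle}.
#' @param params A \linkS4class{MapperParams}.
#' @return data.frame with columns \code{peptide}, \code{intended},
#'   \code{observed}, \code{ok}.
#' @export
verifyCategories <- function(bundle, params = mapperParams()) {
  stopifnot(is(bundle, "GroundTruthBundle"))
  if (length(bundle@labels) == 0L)
    return(data.frame(peptide = character(), intended = character(),
                      observed = character(), ok = logical()))
  idx <- buildIndex(bundle@constructedDb)
  peps <- names(bundle@labels)
  observed <- classifyPeptides(peps, idx, params)
  intended <- unname(bundle@labels)
  ok <- ifelse(intended == "TRAPPING", observed %in% c("TRANS", "NONE"),
               observed == intended)
  data.frame(peptide = peps, intended = intended,
             observed = unname(observed), ok = unname(ok),
             stringsAsFactors = FALSE, row.names = NULL)
}
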
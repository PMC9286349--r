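## Seeded generators for proteomes, immunopeptidome peptide sets, MS2 spectra
## and error-modelled de novo candidate tables. All generators draw from the
## current RNG stream when seed = NULL, so a pipeline can be made fully
## deterministic with a single top-level set.seed().

## sample() treats a length-1 numeric first argument as 1:n; this picks
## uniformly from the elements of `x` regardless of its length
.resample <- function(x, size = 1L, prob = NULL) {
  x[sample.int(length(x), size, prob = prob)]
}

#' Sample a random proteome
#'
#' Generates i.i.d. uniform residues over the 19-letter, isoleucine-free
#' alphabet (the alphabet of an I/L-collapsed database), so downstream I/L
#' collapse is a no-op.
#'
#' @param nProteins Number of entries (>= 1).
#' @param lengthRange Integer(2): protein lengths are uniform on this range.
#' @param seed Optional integer seed; \code{NULL} uses the current RNG state.
#' @return A \linkS4class{Proteome} with accessions \code{SYN0001, ...},
#'   flagged I/L-collapsed.
#' @export
sampleProteome <- function(nProteins, lengthRange = c(80, 200), seed = NULL) {
  stopifnot(nProteins >= 1L)
  if (!is.null(seed)) set.seed(seed)
  lens <- seq.int(lengthRange[1L], lengthRange[2L])[
    sample.int(lengthRange[2L] - lengthRange[1L] + 1L, nProteins,
               replace = TRUE)]
  seqs <- vapply(lens, .randomResidues, character(1L),
                 alphabet = AA_ALPHABET19)
  Proteome(setNames(seqs, sprintf("SYN%04d", seq_len(nProteins))),
           ilCollapsed = TRUE)
}

#' Sample unique peptides from a proteome
#'
#' Draws \code{n} unique substrings: the source protein is sampled with
#' probability proportional to its length, the peptide length uniformly on
#' \code{lengthRange} (8--15-mers by default, the HLA-I size window), and the
#' start position uniformly. Peptides are drawn from disjoint source loci:
#' draws whose source interval overlaps an earlier peptide's interval are
#' rejected, since near-duplicate peptides sharing long prefixes or suffixes
#' cannot be held apart in a constructed category-separated database (any
#' long shared stretch is a valid splice reactant of both peptides).
#'
#' @param proteome A \linkS4class{Proteome}.
#' @param n Number of peptides.
#' @param lengthRange Integer(2), default \code{c(8, 15)}.
#' @param seed Optional integer seed.
#' @param nonNested If \code{TRUE} (default), no sampled peptide is a
#'   substring of another; a ground-truth construction cannot keep a nested
#'   peptide in a lower category than its host, so nested draws are rejected.
#' @return Character vector of \code{n} unique peptides, each a substring of
#'   some protein.
#' @export
samplePeptides <- function(proteome, n, lengthRange = c(8, 15), seed = NULL,
                           nonNested = TRUE) {
  stopifnot(is(proteome, "Proteome"))
  if (!is.null(seed)) set.seed(seed)
  if (n == 0L) return(character())
  seqs <- as.character(proteome@seqs)
  w <- nchar(seqs)
  if (max(w) < lengthRange[1L])
    stop("no protein is long enough for the requested peptide lengths")
  out <- character(0L)
  used <- vector("list", length(seqs))   # occupied [start, end] intervals
  tries <- 0L
  maxTries <- 500L * n
  while (length(out) < n && tries < maxTries) {
    tries <- tries + 1L
    len <- .resample(seq.int(lengthRange[1L], lengthRange[2L]))
    ok <- w >= len
    j <- .resample(which(ok), prob = w[ok])
    s <- sample(w[j] - len + 1L, 1L)
    pep <- unname(substr(seqs[j], s, s + len - 1L))
    clash <- pep %in% out
    if (!clash && length(used[[j]]) > 0L) {
      iv <- used[[j]]
      clash <- any(s <= iv[, 2L] & (s + len - 1L) >= iv[, 1L])
    }
    if (!clash && nonNested && length(out) > 0L) {
      clash <- any(vapply(out, function(o)
        grepl(pep, o, fixed = TRUE) || grepl(o, pep, fixed = TRUE),
        logical(1L)))
    }
    if (!clash) {
      out <- c(out, pep)
      used[[j]] <- rbind(used[[j]], c(s, s + len - 1L))
    }
  }
  if (length(out) < n)
    stop("could not sample ", n, " unique peptides from this proteome")
  out
}

#' Simulate an MS2 spectrum of a peptide
#'
#' Each theoretical singly-charged b/y fragment is observed with probability
#' \code{fragmentDetectProb} and jittered in m/z; a Poisson number of uniform
#' noise peaks is added; intensities are log-normal. The precursor m/z is
#' derived from the peptide's monoisotopic mass and a sampled charge state,
#' with small ppm-scale jitter.
#'
#' @param peptide Peptide sequence (length >= 2).
#' @param model A \linkS4class{SpectrumModel}.
#' @param seed Optional integer seed.
#' @param spectrumId Identifier (default derived from the peptide).
#' @param charge Optional fixed charge; sampled from the model otherwise.
#' @return A \linkS4class{Spectrum}.
#' @export
simulateSpectrum <- function(peptide, model = spectrumModel(), seed = NULL,
                             spectrumId = paste0("spec_", peptide),
                             charge = NULL) {
  stopifnot(nchar(peptide) >= 2L)
  if (!is.null(seed)) set.seed(seed)
  frag <- theoreticalFragments(peptide)
  keep <- runif(length(frag)) < model@fragmentDetectProb
  sigMz <- frag[keep] + rnorm(sum(keep), 0, model@mzJitterSd)
  sigInt <- rlnorm(sum(keep), model@signalMeanLog, model@signalSdLog)
  nNoise <- rpois(1L, model@noiseLambda)
  noiseMz <- runif(nNoise, model@noiseMzRange[1L], model@noiseMzRange[2L])
  noiseInt <- rlnorm(nNoise, model@noiseMeanLog, model@noiseSdLog)
  if (is.null(charge))
    charge <- sample(1:4, 1L, prob = model@chargeProbs)
  m <- peptideMass(peptide)
  mz <- (m + charge * PROTON_MASS) / charge
  mz <- mz * (1 + rnorm(1L, 0, model@precursorPpmSd) * 1e-6)
  Spectrum(spectrumId, mz, charge,
           cbind(mz = c(sigMz, noiseMz), intensity = c(sigInt, noiseInt)))
}

#' Isobaric replacement table
#'
#' Enumerates near-isobaric substitutions between a single residue and an
#' ordered residue pair (e.g. N <-> GG, Q <-> AG) from the monoisotopic mass
#' table, within a mass window.
#'
#' @param tolerance Mass window in Da (default 0.02).
#' @param alphabet Residues to consider (default the 19-letter I-free set).
#' @return data.frame with columns \code{single}, \code{pair},
#'   \code{massDiff}.
#' @export
isobaricReplacements <- function(tolerance = 0.02,
                                 alphabet = AA_ALPHABET19) {
  singles <- alphabet
  pairs <- expand.grid(a = alphabet, b = alphabet,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  pairMass <- AA_MONO_MASS[pairs$a] + AA_MONO_MASS[pairs$b]
  out <- list()
  for (s in singles) {
    d <- abs(AA_MONO_MASS[[s]] - pairMass)
    hit <- which(d <= tolerance & pairs$a != s & pairs$b != s)
    if (length(hit))
      out[[s]] <- data.frame(single = s,
                             pair = paste0(pairs$a[hit], pairs$b[hit]),
                             massDiff = unname(d[hit]),
                             stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(single = character(), pair = character(),
                      massDiff = numeric()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$single, res$pair), , drop = FALSE]
}

## one erroneous variant of `peptide`; returns list(sequence, errorPos)
## errorPos indexes residues of the *variant* that deviate from the truth
.mutatePeptide <- function(peptide, model, alphabet = AA_ALPHABET19,
                           isoTable = NULL) {
  n <- nchar(peptide)
  kind <- sample(names(model@substitutionWeights), 1L,
                 prob = model@substitutionWeights)
  chars <- strsplit(peptide, "")[[1L]]
  if (kind == "swap") {
    cand <- which(chars[-n] != chars[-1L])
    if (length(cand) == 0L) kind <- "single"
  }
  if (kind == "isobaric") {
    if (is.null(isoTable)) isoTable <- isobaricReplacements()
    ## sites: a residue replaceable by a pair, or a pair replaceable by one
    singleSites <- which(chars %in% isoTable$single)
    pairs2 <- paste0(chars[-n], chars[-1L])
    pairSites <- which(pairs2 %in% isoTable$pair)
    if (length(singleSites) + length(pairSites) == 0L) kind <- "single"
  }
  switch(kind,
    single = {
      p <- sample(n, 1L)
      chars[p] <- sample(setdiff(alphabet, chars[p]), 1L)
      list(sequence = paste(chars, collapse = ""), errorPos = p)
    },
    swap = {
      p <- if (length(cand) == 1L) cand else sample(cand, 1L)
      chars[c(p, p + 1L)] <- chars[c(p + 1L, p)]
      list(sequence = paste(chars, collapse = ""), errorPos = c(p, p + 1L))
    },
    isobaric = {
      useSingle <- length(singleSites) > 0L &&
        (length(pairSites) == 0L || runif(1L) < 0.5)
      if (useSingle) {
        p <- if (length(singleSites) == 1L) singleSites else
          sample(singleSites, 1L)
        repl <- isoTable$pair[isoTable$single == chars[p]]
        repl <- if (length(repl) == 1L) repl else sample(repl, 1L)
        seqOut <- paste0(substr(peptide, 1L, p - 1L), repl,
                         substr(peptide, p + 1L, n))
        list(sequence = seqOut, errorPos = c(p, p + 1L))
      } else {
        p <- if (length(pairSites) == 1L) pairSites else sample(pairSites, 1L)
        repl <- isoTable$single[isoTable$pair == pairs2[p]]
        repl <- if (length(repl) == 1L) repl else sample(repl, 1L)
        seqOut <- paste0(substr(peptide, 1L, p - 1L), repl,
                         substr(peptide, p + 2L, n))
        list(sequence = seqOut, errorPos = p)
      }
    })
}

## per-residue LCS draw for a variant; errorPos depressed when localization on
.drawLcs <- function(len, errorPos, model) {
  lcs <- rnorm(len, model@lcsSignalMean, model@lcsSignalSd)
  if (length(errorPos) > 0L) {
    dep <- abs(rnorm(length(errorPos), model@lcsErrorDepressionMean,
                     model@lcsErrorDepressionSd))
    if (model@lcsErrorLocalization) {
      lcs[errorPos] <- lcs[errorPos] - dep
    } else {
      lcs <- lcs - sum(dep) / len
    }
  }
  pmin(pmax(lcs, 0), 100)
}

#' Simulate a de novo candidate list for one spectrum
#'
#' Produces \code{k} ranked candidates for the spectrum of a known peptide:
#' with probability \code{pCorrectRank1} the true sequence is the rank-1
#' candidate (otherwise the true sequence is absent, emulating a failed
#' sequencing run); the remaining candidates are erroneous variants generated
#' by single substitutions, adjacent swaps and isobaric replacements. ALC is
#' the mean of the per-residue LCS values by construction, and candidates are
#' ranked by decreasing ALC.
#'
#' @param truePeptide The peptide that generated the spectrum.
#' @param spectrum The \linkS4class{Spectrum} (supplies the spectrum id).
#' @param model A \linkS4class{DeNovoErrorModel}.
#' @param k Number of candidates (default 5).
#' @param seed Optional integer seed.
#' @param isoTable Precomputed [isobaricReplacements()] table (optional).
#' @return data.frame with columns \code{spectrum_id}, \code{rank},
#'   \code{sequence}, \code{alc}, \code{lcs} (semicolon-joined per-residue
#'   scores).
#' @export
simulateDenovo <- function(truePeptide, spectrum, model = deNovoErrorModel(),
                           k = 5, seed = NULL, isoTable = NULL) {
  stopifnot(k >= 1L)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(isoTable)) isoTable <- isobaricReplacements()
  trueFirst <- runif(1L) < model@pCorrectRank1

  nErr <- if (trueFirst) k - 1L else k
  errs <- vector("list", nErr)
  seen <- if (trueFirst) truePeptide else character()
  for (i in seq_len(nErr)) {
    for (try in 1:20) {
      v <- .mutatePeptide(truePeptide, model, isoTable = isoTable)
      if (!(v$sequence %in% seen)) break
    }
    seen <- c(seen, v$sequence)
    errs[[i]] <- v
  }

  cands <- list()
  if (trueFirst) {
    lcs <- .drawLcs(nchar(truePeptide), integer(), model)
    cands[[1L]] <- list(sequence = truePeptide, lcs = lcs, true = TRUE)
  }
  for (v in errs) {
    lcs <- .drawLcs(nchar(v$sequence), v$errorPos, model)
    cands[[length(cands) + 1L]] <- list(sequence = v$sequence, lcs = lcs,
                                        true = FALSE)
  }
  alc <- vapply(cands, function(c) mean(c$lcs), numeric(1L))
  if (trueFirst && any(alc[-1L] >= alc[1L])) {
    ## enforce the rank-1 outcome: erroneous candidates that outscored the
    ## true sequence are rescaled just below it
    over <- which(alc[-1L] >= alc[1L]) + 1L
    for (j in over) {
      target <- alc[1L] - runif(1L, 0.5, 3)
      cands[[j]]$lcs <- pmin(pmax(cands[[j]]$lcs * target / alc[j], 0), 100)
      alc[j] <- mean(cands[[j]]$lcs)
    }
  }
  ord <- order(alc, decreasing = TRUE)
  data.frame(
    spectrum_id = spectrumId(spectrum),
    rank = seq_len(k),
    sequence = vapply(cands[ord], `[[`, character(1L), "sequence"),
    alc = round(alc[ord], 2L),
    lcs = vapply(cands[ord], function(c)
      paste(sprintf("%.2f", c$lcs), collapse = ";"), character(1L)),
    stringsAsFactors = FALSE)
}

#' Default configuration for a synthetic benchmark dataset
#'
#' Problem sizes are chosen as a desk-scale rendition of a constructed HLA-I
#' immunopeptidome experiment: a few-thousand-residue reference database and a
#' peptide set split in equal thirds across the non-spliced, cis-spliced and
#' trapping categories, one MS2 spectrum per peptide, five de novo candidates
#' per spectrum.
#'
#' @param nProteins Number of reference proteins (default 60).
#' @param proteinLengthRange Default \code{c(80, 200)}.
#' @param nPeptides Number of target peptides (default 120).
#' @param peptideLengthRange Default \code{c(8, 15)}.
#' @param spectrumModel A \linkS4class{SpectrumModel}.
#' @param denovoModel A \linkS4class{DeNovoErrorModel}.
#' @param maxIntervening Cis intervening cap (default 25).
#' @param denovoK Candidates per spectrum (default 5).
#' @param maxRetries Ground-truth plant retries (default 100).
#' @return A named list understood by [buildBenchmarkDataset()].
#' @export
benchmarkConfig <- function(nProteins = 60, proteinLengthRange = c(80, 200),
                            nPeptides = 120, peptideLengthRange = c(8, 15),
                            spectrumModel = SpliceBench::spectrumModel(),
                            denovoModel = deNovoErrorModel(),
                            maxIntervening = 25, denovoK = 5,
                            maxRetries = 100) {
  list(nProteins = nProteins, proteinLengthRange = proteinLengthRange,
       nPeptides = nPeptides, peptideLengthRange = peptideLengthRange,
       spectrumModel = spectrumModel, denovoModel = denovoModel,
       maxIntervening = maxIntervening, denovoK = denovoK,
       maxRetries = maxRetries)
}

#' Build a complete synthetic benchmark dataset
#'
#' End-to-end fixture generation: random proteome, target peptide sampling,
#' constructed ground-truth database (equal thirds non-spliced / cis /
#' trapping), one simulated MS2 spectrum per target peptide, and a de novo
#' candidate table per spectrum. Fully deterministic under \code{seed}.
#'
#' @param config A list from [benchmarkConfig()].
#' @param seed Integer seed.
#' @return A list: \code{bundle} (\linkS4class{GroundTruthBundle}),
#'   \code{spectra} (list of \linkS4class{Spectrum}), \code{denovo}
#'   (candidate data.frame), \code{answerKey} (data.frame spectrum_id,
#'   peptide, category), \code{config}, \code{seed}.
#' @export
buildBenchmarkDataset <- function(config = benchmarkConfig(), seed = 1) {
  set.seed(seed)
  proteome <- sampleProteome(config$nProteins, config$proteinLengthRange)
  peptides <- samplePeptides(proteome, config$nPeptides,
                             config$peptideLengthRange)
  bundle <- buildGroundTruth(
    proteome, peptides,
    groundTruthParams(maxIntervening = config$maxIntervening,
                      maxRetries = config$maxRetries))
  labels <- categoryLabels(bundle)

  isoTable <- isobaricReplacements()
  spectra <- vector("list", length(peptides))
  denovo <- vector("list", length(peptides))
  key <- vector("list", length(peptides))
  for (i in seq_along(peptides)) {
    id <- sprintf("SYNSPEC_%04d", i)
    sp <- simulateSpectrum(peptides[i], config$spectrumModel,
                           spectrumId = id)
    spectra[[i]] <- sp
    denovo[[i]] <- simulateDenovo(peptides[i], sp, config$denovoModel,
                                  k = config$denovoK, isoTable = isoTable)
    key[[i]] <- data.frame(spectrum_id = id, peptide = peptides[i],
                           category = unname(labels[[peptides[i]]]),
                           stringsAsFactors = FALSE)
  }
  list(bundle = bundle, spectra = spectra,
       denovo = do.call(rbind, denovo), answerKey = do.call(rbind, key),
       config = config, seed = seed)
}
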
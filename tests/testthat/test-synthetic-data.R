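test_that("proteome sampling is seeded, sized and uniform", {
  p <- sampleProteome(5, c(50, 100), seed = 1)
  expect_identical(length(p), 5L)
  w <- nchar(proteinSequences(p))
  expect_true(all(w >= 50L & w <= 100L))
  expect_true(isIlCollapsed(p))

  expect_identical(proteinSequences(sampleProteome(5, c(50, 100), seed = 1)),
                   proteinSequences(p))

  big <- sampleProteome(40, c(300, 400), seed = 9)
  counts <- table(strsplit(paste(proteinSequences(big), collapse = ""),
                           "")[[1L]])
  expect_identical(length(counts), 19L)       # I never appears
  expect_gt(stats::chisq.test(counts)$p.value, 0.01)
})

test_that("peptide sampling draws unique non-nested substrings", {
  p <- sampleProteome(20, c(80, 150), seed = 2)
  peps <- samplePeptides(p, 50, seed = 3)
  expect_identical(length(peps), 50L)
  expect_false(anyDuplicated(peps) > 0L)
  seqs <- proteinSequences(p)
  for (pep in peps)
    expect_true(any(grepl(pep, seqs, fixed = TRUE)))
  ## no peptide contains another
  for (i in seq_along(peps))
    expect_false(any(grepl(peps[i], peps[-i], fixed = TRUE)))

  expect_identical(samplePeptides(p, 0), character())
  expect_identical(samplePeptides(p, 10, seed = 4),
                   samplePeptides(p, 10, seed = 4))
  tiny <- Proteome(c(P1 = "MKLV"))
  expect_error(samplePeptides(tiny, 1), "long enough")
})

test_that("spectrum simulation respects the peak model", {
  pep <- "MKGALWEQ"
  clean <- spectrumModel(fragmentDetectProb = 1, noiseLambda = 0,
                         mzJitterSd = 0)
  sp <- simulateSpectrum(pep, clean, seed = 5)
  expect_identical(nrow(peaks(sp)), 14L)

  none <- simulateSpectrum(pep, spectrumModel(fragmentDetectProb = 0,
                                              noiseLambda = 0), seed = 5)
  expect_identical(nrow(peaks(none)), 0L)

  ## jittered signal stays within the fragment tolerance of theory
  jit <- simulateSpectrum(pep, spectrumModel(fragmentDetectProb = 1,
                                             noiseLambda = 0,
                                             mzJitterSd = 0.005), seed = 6)
  frag <- theoreticalFragments(pep)
  d <- vapply(peaks(jit)[, 1L], function(mz) min(abs(mz - frag)),
              numeric(1L))
  expect_true(all(d <= 0.02))

  ## precursor m/z encodes the peptide mass at the sampled charge
  z <- precursorCharge(sp)
  M <- z * precursorMz(sp) - z * 1.00727646688
  expect_equal(M, peptideMass(pep), tolerance = 1e-4)
})

test_that("de novo simulation produces ranked, error-modelled candidates", {
  pep <- "MKGALWEQ"
  sp <- simulateSpectrum(pep, seed = 7)
  sure <- deNovoErrorModel(pCorrectRank1 = 1)
  for (s in 1:10) {
    dn <- simulateDenovo(pep, sp, sure, k = 5, seed = s)
    expect_identical(nrow(dn), 5L)
    expect_identical(dn$sequence[1L], pep)
    expect_identical(dn$rank, 1:5)
    expect_true(all(diff(dn$alc) <= 0))
    ## the ALC invariant: mean of the per-residue scores, within rounding
    mu <- vapply(strsplit(dn$lcs, ";"), function(v) mean(as.numeric(v)),
                 numeric(1L))
    expect_true(all(abs(mu - dn$alc) <= 0.011))
    expect_identical(nchar(dn$sequence),
                     lengths(strsplit(dn$lcs, ";")))
  }
})

test_that("erroneous residues depress local confidence where they occur", {
  pep <- "MKGALWEQV"
  sp <- simulateSpectrum(pep, seed = 8)
  model <- deNovoErrorModel(pCorrectRank1 = 1)
  set.seed(99)
  hits <- 0L
  n <- 1000L
  for (i in seq_len(n)) {
    dn <- simulateDenovo(pep, sp, model, k = 2)
    mins <- vapply(strsplit(dn$lcs, ";"), function(v) min(as.numeric(v)),
                   numeric(1L))
    if (mins[dn$sequence != pep][1L] < mins[dn$sequence == pep][1L])
      hits <- hits + 1L
  }
  expect_gte(hits / n, 0.95)
})

test_that("isobaric replacements are generated from the mass table", {
  iso <- isobaricReplacements()
  expect_true(any(iso$single == "N" & iso$pair == "GG"))
  expect_true(any(iso$single == "Q" & iso$pair == "AG"))
  expect_true(any(iso$single == "Q" & iso$pair == "GA"))
  expect_true(all(iso$massDiff <= 0.02))
  ## W vs SV sits just outside the default 0.02 Da window
  expect_false(any(iso$single == "W" & iso$pair %in% c("SV", "VS")))
  expect_true(any(isobaricReplacements(0.025)$single == "W"))
})

test_that("the end-to-end dataset builder is balanced and deterministic", {
  cfg <- benchmarkConfig(nProteins = 30, nPeptides = 30)
  ds <- buildBenchmarkDataset(cfg, seed = 13)
  counts <- table(ds$answerKey$category)
  expect_identical(as.integer(counts[c("CIS", "NONSPLICED", "TRAPPING")]),
                   rep(10L, 3L))
  expect_identical(length(ds$spectra), 30L)
  expect_identical(nrow(ds$denovo), 150L)

  ## non-spliced answer-key peptides classify non-spliced in the
  ## constructed database
  idx <- buildIndex(constructedDb(ds$bundle))
  ns <- ds$answerKey$peptide[ds$answerKey$category == "NONSPLICED"]
  expect_true(all(classifyPeptides(ns, idx) == "NONSPLICED"))

  ## byte-identical fixture files under the same seed
  ds2 <- buildBenchmarkDataset(cfg, seed = 13)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  writeMgf(ds$spectra, f1); writeMgf(ds2$spectra, f2)
  expect_identical(readLines(f1), readLines(f2))
  g1 <- withr::local_tempfile(); g2 <- withr::local_tempfile()
  writeDeNovoTable(ds$denovo, g1); writeDeNovoTable(ds2$denovo, g2)
  expect_identical(readLines(g1), readLines(g2))
})

test_that("MGF and table IO round-trip", {
  set.seed(21)
  spectra <- lapply(c("MKGALWEQ", "ACDEFGHK"), function(p)
    simulateSpectrum(p, spectrumId = paste0("rt_", p)))
  f <- withr::local_tempfile(fileext = ".mgf")
  writeMgf(spectra, f)
  back <- readMgf(f)
  expect_identical(length(back), 2L)
  expect_identical(spectrumId(back[[1L]]), "rt_MKGALWEQ")
  expect_identical(precursorCharge(back[[1L]]),
                   precursorCharge(spectra[[1L]]))
  expect_equal(precursorMz(back[[1L]]), precursorMz(spectra[[1L]]),
               tolerance = 1e-5)
  expect_identical(nrow(peaks(back[[2L]])), nrow(peaks(spectra[[2L]])))

  dn <- simulateDenovo("MKGALWEQ", spectra[[1L]], seed = 3)
  g <- withr::local_tempfile(fileext = ".tsv")
  writeDeNovoTable(dn, g)
  dn2 <- readDeNovoTable(g)
  expect_identical(dn2$sequence, dn$sequence)

  ## the reader enforces the ALC/LCS consistency contract
  bad <- dn
  bad$alc[1L] <- bad$alc[1L] + 5
  writeDeNovoTable(bad, g)
  expect_error(readDeNovoTable(g), "mean LCS")
})
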
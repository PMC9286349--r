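## toy reference used throughout: "LPETG" is a substring of P1; "MKGAL" and
## "MKTGA" are cis-explainable within P1; "MKAAAA" needs P1 + P2 (trans)
toyIndex <- function() {
  buildIndex(Proteome(c(P1 = "MKLLPETGAL", P2 = "AAAAGGGG"),
                      ilCollapsed = TRUE))
}

denovoRow <- function(id, rank, seq, alc, lcs = NULL) {
  if (is.null(lcs)) lcs <- rep(alc, nchar(seq))
  data.frame(spectrum_id = id, rank = rank, sequence = seq, alc = alc,
             lcs = paste(sprintf("%.2f", lcs), collapse = ";"),
             stringsAsFactors = FALSE)
}

test_that("the ALC cutoff is a quantile of agreeing rank-1 candidates", {
  dn <- do.call(rbind, lapply(1:5, function(i)
    denovoRow(paste0("S", i), 1L, "LPETG", c(80, 85, 90, 95, 100)[i])))
  confident <- setNames(rep("LPETG", 5L), paste0("S", 1:5))
  expect_identical(computeAlcCutoff(dn, confident, quantile = 0), 80)

  dnEq <- do.call(rbind, lapply(1:4, function(i)
    denovoRow(paste0("S", i), 1L, "LPETG", 90)))
  confEq <- setNames(rep("LPETG", 4L), paste0("S", 1:4))
  for (q in c(0, 0.05, 0.5, 1))
    expect_identical(computeAlcCutoff(dnEq, confEq, q), 90)

  ## only agreeing spectra count
  dn$sequence[2L] <- "MKGAL"
  expect_identical(computeAlcCutoff(dn, confident, quantile = 0), 80)

  ## seeded draw against an explicit sort-and-index oracle
  set.seed(55)
  alcs <- round(runif(100, 60, 100), 2L)
  dnBig <- do.call(rbind, lapply(1:100, function(i)
    denovoRow(sprintf("T%03d", i), 1L, "LPETG", alcs[i])))
  confBig <- setNames(rep("LPETG", 100L), sprintf("T%03d", 1:100))
  expect_identical(computeAlcCutoff(dnBig, confBig, quantile = 0.05),
                   sort(alcs)[ceiling(0.05 * 100)])

  expect_error(computeAlcCutoff(dnBig, c(ZZZ = "LPETG")), "manually")
})

test_that("AP selection follows the discard hierarchy", {
  idx <- toyIndex()

  ## non-spliced candidate kills the whole spectrum
  dn1 <- rbind(denovoRow("S1", 1L, "MKGAL", 90),
               denovoRow("S1", 2L, "LPETG", 85))
  expect_identical(nrow(apSelectCandidates(dn1, idx, 50)), 0L)

  ## highest-ALC cis wins over a better-scoring trans candidate
  dn2 <- rbind(denovoRow("S2", 1L, "MKAAAA", 99),
               denovoRow("S2", 2L, "MKTGA", 92),
               denovoRow("S2", 3L, "MKGAL", 88))
  sel2 <- apSelectCandidates(dn2, idx, 50)
  expect_identical(sel2$sequence, "MKTGA")
  expect_identical(sel2$category, "CIS")

  ## trans is used only when no cis exists
  dn3 <- rbind(denovoRow("S3", 1L, "MKAAAA", 90),
               denovoRow("S3", 2L, "WWWWWW", 95))
  sel3 <- apSelectCandidates(dn3, idx, 50)
  expect_identical(sel3$sequence, "MKAAAA")
  expect_identical(sel3$category, "TRANS")

  ## unexplainable spectra are dropped
  dn4 <- denovoRow("S4", 1L, "WWWWWW", 95)
  expect_identical(nrow(apSelectCandidates(dn4, idx, 50)), 0L)

  ## the ALC filter is strict (> cutoff)
  dn5 <- denovoRow("S5", 1L, "MKGAL", 80)
  expect_identical(nrow(apSelectCandidates(dn5, idx, 80)), 0L)
  expect_identical(nrow(apSelectCandidates(dn5, idx, 79.9)), 1L)

  ## spectrum exclusion list
  expect_identical(nrow(apSelectCandidates(dn2, idx, 50,
                                           excludeSpectra = "S2")), 0L)

  ## at most one candidate per spectrum on a mixed table
  mixed <- rbind(dn2, dn3)
  selM <- apSelectCandidates(mixed, idx, 50)
  expect_identical(nrow(selM), 2L)
  expect_false(anyDuplicated(selM$spectrum_id) > 0L)
})

test_that("MBS selection demands per-residue confidence and cis mapping", {
  idx <- toyIndex()

  ## one residue at 79 fails the per-residue gate
  lcs79 <- c(95, 95, 79, 95, 95)
  dn1 <- denovoRow("S1", 1L, "MKGAL", mean(lcs79), lcs79)
  expect_identical(nrow(mbsSelectCandidates(dn1, idx, 80)), 0L)
  expect_identical(nrow(mbsSelectCandidates(dn1, idx, 79)), 1L)

  ## cis only with intervening 26 is rejected at the 25-residue cap
  far <- buildIndex(Proteome(
    c(P3 = paste0("MKW", strrep("Q", 26), "GALPP")), ilCollapsed = TRUE))
  dn2 <- denovoRow("S2", 1L, "MKWGAL", 95)
  expect_identical(nrow(mbsSelectCandidates(dn2, far, 80)), 0L)
  expect_identical(nrow(mbsSelectCandidates(dn2, far, 80,
                                            mapperParams(maxIntervening = 26))),
                   1L)

  ## non-spliced and trans candidates are never retained
  dn3 <- rbind(denovoRow("S3", 1L, "LPETG", 95),
               denovoRow("S3", 2L, "MKAAAA", 95))
  expect_identical(nrow(mbsSelectCandidates(dn3, idx, 80)), 0L)

  ## several cis candidates of one spectrum may be retained
  dn4 <- rbind(denovoRow("S4", 1L, "MKGAL", 95),
               denovoRow("S4", 2L, "MKTGA", 93))
  expect_identical(nrow(mbsSelectCandidates(dn4, idx, 80)), 2L)
})

test_that("target database assembly concatenates or appends per mode", {
  ref <- Proteome(c(P1 = "MKLLPETGAL"), ilCollapsed = TRUE)
  retained <- data.frame(spectrum_id = paste0("S", 1:3), rank = 1L,
                         sequence = c("MKGAL", "MKTGA", "GALMK"),
                         alc = 90, lcs = "", category = "CIS",
                         stringsAsFactors = FALSE)

  ap <- buildTargetDb(retained, ref, "AP", chunkSize = 25)
  expect_identical(length(splicedEntries(ap)), 1L)
  expect_identical(nchar(as.character(splicedEntries(ap))[[1L]]), 15L)
  expect_identical(as.character(splicedEntries(ap))[[1L]],
                   "MKGALMKTGAGALMK")
  expect_true(startsWith(names(splicedEntries(ap))[1L], "SPLICED_"))

  apChunks <- buildTargetDb(retained[rep(1:3, 10), ], ref, "AP",
                            chunkSize = 25)
  expect_identical(length(splicedEntries(apChunks)), 2L)
  expect_identical(unname(nchar(as.character(splicedEntries(apChunks)))),
                   c(125L, 25L))

  mbs <- buildTargetDb(retained, ref, "MBS")
  expect_identical(length(splicedEntries(mbs)), 3L)
  expect_identical(unname(as.character(splicedEntries(mbs))),
                   retained$sequence)
  expect_identical(provenance(mbs)$entry,
                   names(splicedEntries(mbs)))

  none <- buildTargetDb(retained[0L, ], ref, "MBS")
  expect_identical(length(splicedEntries(none)), 0L)
  expect_identical(proteinSequences(referenceProteome(none)),
                   proteinSequences(ref))
})

test_that("database truth features count candidates correctly", {
  peps12 <- paste0("MKGALWE", c("A", "C", "D", "E", "F", "G", "H", "K",
                                "L", "M", "N", "P"))
  labels <- setNames(rep(c("CIS", "NONSPLICED"), c(8L, 4L)), peps12)
  truth <- new("GroundTruthBundle",
               constructedDb = Proteome(c(P1 = "MKLV"), ilCollapsed = TRUE),
               labels = labels, plants = data.frame(),
               verification = data.frame())
  trueCis <- names(labels)[labels == "CIS"]

  exact <- buildTargetDb(trueCis, Proteome(c(P1 = "MKLV")), "MBS")
  fe <- targetDbFeatures(exact, truth)
  expect_identical(fe$precision_potential, 1)
  expect_identical(fe$recall_potential, 1)

  junk <- buildTargetDb(c("WWWWW", "YYYYY"), Proteome(c(P1 = "MKLV")), "MBS")
  fj <- targetDbFeatures(junk, truth)
  expect_identical(fj$precision_potential, 0)
  expect_identical(fj$recall_potential, 0)

  fakes <- paste0("WYWYWY", c("A", "C", "D", "E", "F", "G"))
  mix <- buildTargetDb(c(trueCis[1:4], fakes),
                       Proteome(c(P1 = "MKLV")), "MBS")
  fm <- targetDbFeatures(mix, truth)
  expect_identical(fm$n_candidates, 10L)
  expect_identical(fm$n_true_candidates, 4L)
  expect_identical(fm$n_true_total, 8L)
  expect_identical(fm$precision_potential, 0.4)
  expect_identical(fm$recall_potential, 0.5)
})
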
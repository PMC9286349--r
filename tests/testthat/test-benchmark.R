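## a hand-built PSM set with known correctness structure:
## 10 target PSMs over 12 keyed spectra; 7 correct, 3 wrong
handPsms <- function() {
  key <- data.frame(
    spectrum_id = sprintf("H%02d", 1:12),
    peptide = paste0("MKGALWE", c("A", "C", "D", "E", "F", "G", "H", "K",
                                  "L", "M", "N", "P")),
    category = rep(c("NONSPLICED", "CIS", "TRAPPING"), each = 4L),
    stringsAsFactors = FALSE)
  psms <- data.frame(
    spectrum_id = key$spectrum_id[1:10],
    peptide = key$peptide[1:10],
    score = c(12, 11, 10, 9, 8, 7, 6, 5, 4, 3),
    is_decoy = FALSE,
    assigned_category = c("NONSPLICED", "NONSPLICED", "NONSPLICED",
                          "NONSPLICED", "CIS", "CIS", "CIS", "CIS",
                          "TRANS", "TRANS"),
    stringsAsFactors = FALSE)
  ## break three of them: wrong sequence (H02), wrong category (H05),
  ## wrong sequence (H09)
  psms$peptide[2L] <- "WWWWWWWW"
  psms$assigned_category[5L] <- "NONSPLICED"
  psms$peptide[9L] <- "YYYYYYYY"
  list(psms = psms, key = key)
}

test_that("precision and recall match hand counts", {
  h <- handPsms()
  pr <- precisionRecall(h$psms, h$key, thresholds = 0)

  ns <- pr[pr$category == "NONSPLICED", ]
  ## assigned to NONSPLICED: H01..H04 plus miscategorised H05
  expect_identical(ns$n_assigned, 5L)
  expect_identical(ns$n_correct, 3L)     # H01, H03, H04
  expect_identical(ns$precision, 3 / 5)
  expect_identical(ns$recall, 3 / 4)

  cis <- pr[pr$category == "CIS", ]
  expect_identical(cis$n_assigned, 3L)   # H06..H08
  expect_identical(cis$n_correct, 3L)
  expect_identical(cis$precision, 1)
  expect_identical(cis$recall, 3 / 4)

  all <- pr[pr$category == "ALL", ]
  expect_identical(all$n_correct, 7L)
  expect_identical(all$precision, 0.7)

  ## sequence correctness is judged after I/L collapse
  ilKey <- h$key
  ilKey$peptide[1L] <- chartr("L", "I", ilKey$peptide[1L])
  prIl <- precisionRecall(h$psms, ilKey, thresholds = 0)
  expect_identical(prIl[prIl$category == "NONSPLICED", "n_correct"], 3L)

  ## thresholds with nothing assigned are dropped, and a missing
  ## spectrum is an error
  expect_identical(nrow(precisionRecall(h$psms, h$key, thresholds = 99)),
                   0L)
  expect_error(precisionRecall(rbind(h$psms,
                                     within(h$psms[1L, ],
                                            spectrum_id <- "GHOST")),
                               h$key, 0),
               "GHOST")
})

test_that("recall never decreases as the threshold loosens", {
  h <- handPsms()
  pr <- precisionRecall(h$psms, h$key, thresholds = c(0, 4, 8, 11))
  for (cat in unique(pr$category)) {
    sub <- pr[pr$category == cat, ]
    sub <- sub[order(sub$threshold), ]
    expect_true(all(diff(sub$recall) <= 0))
  }
})

test_that("the misassignment table counts trapping spectra faithfully", {
  h <- handPsms()
  tab <- misassignmentTable(h$psms, h$key, 0)
  expect_identical(tab["TRAPPING", "TRANS"], 2L)
  expect_identical(tab["TRAPPING", "CIS"], 0L)
  expect_identical(tab["NONSPLICED", "NONSPLICED"], 4L)
  expect_identical(tab["CIS", "NONSPLICED"], 1L)
  expect_identical(sum(tab), 10L)

  ## a perfect engine leaves the trapping misassignment cells empty
  perfect <- h$psms[1:4, ]
  tabP <- misassignmentTable(perfect, h$key, 0)
  expect_identical(unname(tabP["TRAPPING", c("NONSPLICED", "CIS")]),
                   c(0L, 0L))

  ## every trapping spectrum assigned a cis sequence
  trap <- data.frame(spectrum_id = sprintf("H%02d", 9:12),
                     peptide = "MKGALWEA", score = 10, is_decoy = FALSE,
                     assigned_category = "CIS", stringsAsFactors = FALSE)
  expect_identical(misassignmentTable(trap, h$key, 0)["TRAPPING", "CIS"],
                   4L)

  ## a seeded noisy table equals a brute-force recount
  set.seed(44)
  noisy <- h$psms[sample(10L, 30L, replace = TRUE), ]
  noisy$spectrum_id <- sample(h$key$spectrum_id, 30L, replace = TRUE)
  noisy$score <- runif(30L, 0, 15)
  thr <- 6
  tabN <- misassignmentTable(noisy, h$key, thr)
  for (tc in rownames(tabN)) for (ac in colnames(tabN)) {
    manual <- 0L
    for (i in seq_len(nrow(noisy))) {
      if (noisy$score[i] < thr) next
      trueCat <- h$key$category[h$key$spectrum_id == noisy$spectrum_id[i]]
      if (trueCat == tc && noisy$assigned_category[i] == ac)
        manual <- manual + 1L
    }
    expect_identical(unname(tabN[tc, ac]), manual)
  }
})

test_that("the FDR-PSM curve tracks brute-force recounts", {
  set.seed(45)
  psms <- data.frame(score = runif(300, 0, 20), is_decoy = runif(300) < 0.25)
  thr <- c(2, 5, 9, 14)
  curve <- fdrPsmCurve(psms, thr)
  expect_identical(curve$n_assigned,
                   vapply(thr, function(t)
                     sum(psms$score >= t & !psms$is_decoy), integer(1L)))
  expect_true(all(diff(curve$n_assigned) <= 0L))

  clean <- psms[!psms$is_decoy, ]
  expect_true(all(fdrPsmCurve(clean, thr)$fdr_percent == 0))
})

test_that("spectrum features capture coverage, noise and hydropathy", {
  pep <- "MKGALWEQ"
  sp <- perfectSpectrum(pep)
  fe <- spectrumFeatures(sp, pep)
  expect_identical(fe$ion_coverage, 1)
  expect_identical(fe$peptide_length, 8L)
  expect_identical(fe$snr, Inf)          # every peak matches

  fe0 <- spectrumFeatures(sp, "DDDDDDDD")
  expect_identical(fe0$ion_coverage, 0)

  ## hydrophobic vs acidic peptides on the Kyte-Doolittle scale
  hydro <- spectrumFeatures(sp, "GLGAVLKVLTTGL")$hydrophobicity
  acid <- spectrumFeatures(sp, "DEDEDE")$hydrophobicity
  expect_gt(hydro, acid)
  expect_equal(acid, mean(c(-3.5, -3.5)), tolerance = 1e-9)

  ## median matched over median unmatched intensity
  frag <- theoreticalFragments("GAS")
  pk <- cbind(mz = c(frag[["b1"]], 200, 400),
              intensity = c(90, 10, 30))
  spn <- Spectrum("snr", 300, 1L, pk)
  expect_equal(spectrumFeatures(spn, "GAS")$snr, 90 / 20, tolerance = 1e-9)
})
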
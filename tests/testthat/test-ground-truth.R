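test_that("target partition is balanced, seeded and guards duplicates", {
  peps9 <- sprintf("PEPTIDE%02d", 1:9)
  part <- partitionTargets(peps9, groundTruthParams(seed = 5))
  expect_identical(lengths(part),
                   c(NONSPLICED = 3L, CIS = 3L, TRAPPING = 3L))
  expect_setequal(unlist(part), peps9)

  part10 <- partitionTargets(sprintf("PEPTIDE%02d", 1:10),
                             groundTruthParams(seed = 5))
  expect_identical(sort(unname(lengths(part10))), c(3L, 3L, 4L))

  expect_identical(partitionTargets(peps9, groundTruthParams(seed = 5)),
                   part)
  expect_error(partitionTargets(c("AA", "AA"), groundTruthParams()),
               "duplicate")

  skew <- partitionTargets(peps9,
                           groundTruthParams(seed = 1,
                                             categoryWeights = c(1, 0, 0)))
  expect_identical(lengths(skew),
                   c(NONSPLICED = 9L, CIS = 0L, TRAPPING = 0L))
})

test_that("elision removes targets while preserving lengths", {
  p <- Proteome(c(P1 = "AAPEPTLDEKK"))
  out <- elideTargets(p, "PEPTLDE", groundTruthParams(seed = 2))
  s <- unname(proteinSequences(out))
  expect_identical(nchar(s), 11L)
  expect_false(grepl("PEPTLDE", s, fixed = TRUE))

  ## absent target leaves the database untouched
  expect_identical(
    proteinSequences(elideTargets(p, "WWWWWW", groundTruthParams(seed = 2))),
    proteinSequences(p))

  ## overlapping occurrences of two targets: both must vanish
  p2 <- Proteome(c(P1 = "GGMKLPETGAAGG"))
  out2 <- elideTargets(p2, c("MKLPETG", "LPETGAA"),
                       groundTruthParams(seed = 9))
  s2 <- unname(proteinSequences(out2))
  expect_identical(nchar(s2), 13L)
  expect_false(grepl("MKLPETG", s2, fixed = TRUE))
  expect_false(grepl("LPETGAA", s2, fixed = TRUE))

  set.seed(61)
  rp <- sampleProteome(20, c(60, 150))
  targets <- samplePeptides(rp, 15)
  el <- elideTargets(rp, targets, groundTruthParams(seed = 3))
  expect_identical(nchar(proteinSequences(el)),
                   nchar(proteinSequences(rp)))
  for (t in targets)
    expect_false(any(grepl(t, proteinSequences(el), fixed = TRUE)))
})

test_that("planting appends targets in the category-specific form", {
  set.seed(17)
  p <- sampleProteome(10, c(40, 80))

  pl <- plantTarget(p, "LPETGALW", "NONSPLICED", groundTruthParams(seed = 1))
  host <- proteinSequences(pl$proteome)[[pl$record$host1]]
  if (pl$record$terminus1 == "C") expect_true(endsWith(host, "LPETGALW"))
  else expect_true(startsWith(host, "LPETGALW"))

  pl2 <- plantTarget(p, "MKWGALQR", "CIS", groundTruthParams(seed = 2))
  rec <- pl2$record
  block <- paste0(substr("MKWGALQR", 1, rec$splitPoint), rec$interveningSeq,
                  substr("MKWGALQR", rec$splitPoint + 1, 8))
  host2 <- proteinSequences(pl2$proteome)[[rec$host1]]
  expect_true(grepl(block, host2, fixed = TRUE))
  expect_gte(nchar(rec$interveningSeq), 1L)
  expect_lte(nchar(rec$interveningSeq), 25L)
  expect_identical(category(classifyPeptide("MKWGALQR",
                                            buildIndex(pl2$proteome))),
                   "CIS")

  pl3 <- plantTarget(p, "MKWGALQR", "TRAPPING", groundTruthParams(seed = 3))
  expect_false(pl3$record$host1 == pl3$record$host2)
  expect_error(plantTarget(Proteome(c(P1 = "MKLV")), "MKWGALQR", "TRAPPING",
                           groundTruthParams()),
               "two")
})

test_that("the full construction satisfies its category contract", {
  set.seed(23)
  prot <- sampleProteome(50, c(80, 150))
  peps <- samplePeptides(prot, 30)
  bundle <- buildGroundTruth(prot, peps, groundTruthParams(seed = 7))

  rep1 <- verificationReport(bundle)
  expect_identical(nrow(rep1), 30L)
  expect_true(all(rep1$ok))
  obs <- setNames(rep1$observed, rep1$peptide)
  lab <- categoryLabels(bundle)
  expect_true(all(obs[names(lab)[lab == "NONSPLICED"]] == "NONSPLICED"))
  expect_true(all(obs[names(lab)[lab == "CIS"]] == "CIS"))
  expect_true(all(obs[names(lab)[lab == "TRAPPING"]] %in%
                    c("TRANS", "NONE")))

  ## residue bookkeeping: constructed size = collapsed source + plants
  plants <- plantRecords(bundle)
  expect_identical(
    sum(nchar(proteinSequences(constructedDb(bundle)))),
    sum(nchar(proteinSequences(collapseIL(prot)))) +
      sum(nchar(plants$peptide)) +
      sum(nchar(plants$interveningSeq), na.rm = TRUE))

  ## byte-identical FASTA under the same seed
  b2 <- buildGroundTruth(prot, peps, groundTruthParams(seed = 7))
  f1 <- withr::local_tempfile(fileext = ".fasta")
  f2 <- withr::local_tempfile(fileext = ".fasta")
  writeProteomeFasta(constructedDb(bundle), f1)
  writeProteomeFasta(constructedDb(b2), f2)
  expect_identical(readLines(f1), readLines(f2))

  ## a different seed gives different plants but still verifies
  b3 <- buildGroundTruth(prot, peps, groundTruthParams(seed = 8))
  expect_false(identical(plantRecords(b3), plants))
  expect_true(all(verificationReport(b3)$ok))
})

test_that("an empty target list returns the collapsed database unchanged", {
  set.seed(3)
  prot <- sampleProteome(5, c(30, 60))
  bundle <- buildGroundTruth(prot, character(), groundTruthParams(seed = 1))
  expect_identical(proteinSequences(constructedDb(bundle)),
                   proteinSequences(collapseIL(prot)))
  expect_identical(nrow(verificationReport(bundle)), 0L)
  expect_identical(nrow(verifyCategories(bundle)), 0L)
})

test_that("verification detects a corrupted database", {
  set.seed(37)
  prot <- sampleProteome(30, c(60, 120))
  peps <- samplePeptides(prot, 12)
  bundle <- buildGroundTruth(prot, peps, groundTruthParams(seed = 11))
  lab <- categoryLabels(bundle)
  cisPep <- names(lab)[lab == "CIS"][1L]

  ## re-insert a cis target as a plain substring: it must now be reported
  ## as a NONSPLICED mismatch
  seqs <- proteinSequences(constructedDb(bundle))
  seqs[[1L]] <- paste0(seqs[[1L]], cisPep)
  corrupted <- bundle
  corrupted@constructedDb <- Proteome(seqs, ilCollapsed = TRUE)
  rep2 <- verifyCategories(corrupted)
  row <- rep2[rep2$peptide == cisPep, ]
  expect_identical(row$observed, "NONSPLICED")
  expect_false(row$ok)
})
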
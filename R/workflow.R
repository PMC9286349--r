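## End-to-end AP / MBS workflow driver: first-pass search, spectrum
## exclusion, candidate selection, target-database build, final search, FDR
## filtering and benchmark outputs, with a reproducibility manifest.

#' Assemble a workflow run configuration
#'
#' Inputs may be given either as file paths (FASTA reference, MGF spectra,
#' de novo TSV, optional answer-key TSV) or as an in-memory dataset from
#' [buildBenchmarkDataset()]. Paths are validated here, before any
#' computation.
#'
#' @param workflow \code{"AP"} or \code{"MBS"}.
#' @param dataset Optional list from [buildBenchmarkDataset()].
#' @param proteomePath,mgfPath,denovoPath,answerKeyPath Input file paths
#'   (ignored when \code{dataset} is given; \code{answerKeyPath} optional).
#' @param outDir Output run directory (created; default a fresh tempdir
#'   subdirectory).
#' @param seed Integer seed recorded in the manifest and used for any
#'   randomness.
#' @param search A \linkS4class{SearchParams}.
#' @param mapper A \linkS4class{MapperParams}.
#' @param thresholds Score threshold schedule.
#' @param firstPassFdrPercent Estimated-FDR level defining confident
#'   non-spliced first-pass assignments (default 1).
#' @param finalFdrPercent Estimated-FDR level for the final report
#'   (default 1).
#' @param alcQuantile AP ALC-cutoff quantile (default 0.05).
#' @param lcsMin MBS per-residue LCS minimum (default 80).
#' @param chunkSize AP in-silico protein chunk size (default 25).
#' @return A validated configuration list of class \code{"runConfig"}.
#' @export
runConfig <- function(workflow = c("AP", "MBS"), dataset = NULL,
                      proteomePath = NULL, mgfPath = NULL,
                      denovoPath = NULL, answerKeyPath = NULL,
                      outDir = NULL, seed = 1,
                      search = searchParams(), mapper = mapperParams(),
                      thresholds = defaultThresholds(),
                      firstPassFdrPercent = 1, finalFdrPercent = 1,
                      alcQuantile = 0.05, lcsMin = 80, chunkSize = 25) {
  workflow <- match.arg(workflow)
  if (is.null(dataset)) {
    for (p in list(proteome = proteomePath, mgf = mgfPath,
                   denovo = denovoPath)) {
      if (is.null(p)) stop("either 'dataset' or all of proteomePath/",
                           "mgfPath/denovoPath must be supplied")
    }
    for (p in c(proteomePath, mgfPath, denovoPath, answerKeyPath)) {
      if (!file.exists(p)) stop("input path does not exist: ", p)
    }
  }
  if (is.null(outDir))
    outDir <- file.path(tempdir(), paste0("splicebench_",
                                          format(seed, scientific = FALSE)))
  structure(list(workflow = workflow, dataset = dataset,
                 proteomePath = proteomePath, mgfPath = mgfPath,
                 denovoPath = denovoPath, answerKeyPath = answerKeyPath,
                 outDir = outDir, seed = as.integer(seed), search = search,
                 mapper = mapper, thresholds = thresholds,
                 firstPassFdrPercent = firstPassFdrPercent,
                 finalFdrPercent = finalFdrPercent,
                 alcQuantile = alcQuantile, lcsMin = lcsMin,
                 chunkSize = chunkSize),
            class = "runConfig")
}

#' Run an AP or MBS workflow end to end
#'
#' Stages: (1) first-pass search of all spectra against the reference
#' database; (2) spectra confidently assigned as non-spliced peptides at the
#' first-pass FDR level are excluded from de novo candidate selection and
#' define the ALC-cutoff calibration set; (3) AP or MBS candidate selection;
#' (4) target-database build; (5) final concatenated target-decoy search;
#' (6) FDR sweep and threshold selection; (7) benchmark outputs when an
#' answer key is available. All tables, the target database FASTA and a
#' manifest (package version, parameters, seed, input digests) are written
#' to the run directory.
#'
#' @param config A [runConfig()].
#' @return Invisibly, a list with the run directory, all intermediate
#'   objects (first-pass PSMs, retained candidates, target database, final
#'   PSMs, sweep, chosen threshold) and benchmark tables.
#' @export
runWorkflow <- function(config) {
  stopifnot(inherits(config, "runConfig"))
  set.seed(config$seed)
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  inputDir <- file.path(config$outDir, "inputs")
  dir.create(inputDir, showWarnings = FALSE)

  ## ---- stage 0: inputs ----
  if (!is.null(config$dataset)) {
    ds <- config$dataset
    reference <- constructedDb(ds$bundle)
    spectra <- ds$spectra
    denovo <- ds$denovo
    answerKey <- ds$answerKey
    bundle <- ds$bundle
  } else {
    reference <- readProteomeFasta(config$proteomePath, ilCollapsed = FALSE)
    if (any(grepl("I", proteinSequences(reference), fixed = TRUE)))
      reference <- collapseIL(reference)
    else reference <- Proteome(proteinSequences(reference),
                               ilCollapsed = TRUE)
    spectra <- readMgf(config$mgfPath)
    denovo <- readDeNovoTable(config$denovoPath)
    answerKey <- if (!is.null(config$answerKeyPath))
      readAnswerKey(config$answerKeyPath) else NULL
    bundle <- NULL
  }
  writeProteomeFasta(reference, file.path(inputDir, "reference.fasta"))
  writeMgf(spectra, file.path(inputDir, "spectra.mgf"))
  writeDeNovoTable(denovo, file.path(inputDir, "denovo.tsv"))
  if (!is.null(answerKey))
    writeAnswerKey(answerKey, file.path(inputDir, "answer_key.tsv"))

  ## ---- stage 1: first-pass search against the reference ----
  firstPsms <- searchSpectra(spectra, reference, config$search,
                             config$mapper)
  firstSweep <- thresholdSweep(firstPsms, config$thresholds)
  firstThr <- pickThresholdAtFdr(firstSweep, config$firstPassFdrPercent)
  confident <- firstPsms[!firstPsms$is_decoy &
                           firstPsms$score >= firstThr$threshold &
                           firstPsms$assigned_category == "NONSPLICED", ,
                         drop = FALSE]
  excludeSpectra <- confident$spectrum_id
  confidentMap <- setNames(confident$peptide, confident$spectrum_id)

  ## ---- stage 2/3: candidate selection ----
  refIndex <- buildIndex(reference)
  if (config$workflow == "AP") {
    alcCutoff <- computeAlcCutoff(denovo, confidentMap, config$alcQuantile)
    retained <- apSelectCandidates(denovo, refIndex, alcCutoff,
                                   config$mapper, excludeSpectra)
  } else {
    alcCutoff <- NA_real_
    retained <- mbsSelectCandidates(denovo, refIndex, config$lcsMin,
                                    config$mapper, excludeSpectra)
  }

  ## ---- stage 4: target database ----
  targetDb <- buildTargetDb(retained, reference, config$workflow,
                            config$chunkSize)
  writeProteomeFasta(.searchTargets(targetDb),
                     file.path(config$outDir, "target_db.fasta"))

  ## ---- stage 5/6: final search and FDR ----
  finalPsms <- searchSpectra(spectra, targetDb, config$search,
                             config$mapper)
  finalSweep <- thresholdSweep(finalPsms, config$thresholds)
  finalThr <- pickThresholdAtFdr(finalSweep, config$finalFdrPercent)
  writePsmTable(finalPsms, file.path(config$outDir, "psms.tsv"))
  write.table(finalSweep, file.path(config$outDir, "fdr_sweep.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  ## ---- stage 7: benchmark outputs ----
  pr <- mis <- curve <- features <- NULL
  if (!is.null(answerKey)) {
    pr <- precisionRecall(finalPsms, answerKey, config$thresholds)
    mis <- misassignmentTable(finalPsms, answerKey, finalThr$threshold)
    curve <- fdrPsmCurve(finalPsms, config$thresholds)
    write.table(pr, file.path(config$outDir, "pr.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(as.data.frame.matrix(mis),
                file.path(config$outDir, "misassignment.tsv"), sep = "\t",
                quote = FALSE, row.names = TRUE, col.names = NA)
    write.table(curve, file.path(config$outDir, "fdr_psm_curve.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(bundle)) {
    features <- targetDbFeatures(targetDb, bundle)
    write.table(features, file.path(config$outDir, "target_db_features.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  ## ---- manifest ----
  inputFiles <- list.files(inputDir, full.names = TRUE)
  manifest <- list(
    package = "SpliceBench",
    version = as.character(utils::packageVersion("SpliceBench")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    workflow = config$workflow, seed = config$seed,
    parameters = list(
      precursorTolPpm = config$search@precursorTolPpm,
      fragmentTolDa = config$search@fragmentTolDa,
      peptideLenRange = config$search@peptideLenRange,
      maxIntervening = config$mapper@maxIntervening,
      thresholds = config$thresholds,
      firstPassFdrPercent = config$firstPassFdrPercent,
      finalFdrPercent = config$finalFdrPercent,
      alcQuantile = config$alcQuantile, alcCutoff = alcCutoff,
      lcsMin = config$lcsMin, chunkSize = config$chunkSize),
    inputs = as.list(setNames(unname(tools::md5sum(inputFiles)),
                              basename(inputFiles))),
    finalThreshold = finalThr$threshold,
    finalFdrPercent = finalThr$fdr_percent,
    nPsms = nrow(finalPsms), nCandidates = nrow(retained))
  jsonlite::write_json(manifest, file.path(config$outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(outDir = config$outDir, reference = reference,
                 firstPsms = firstPsms, firstThreshold = firstThr,
                 excludeSpectra = excludeSpectra, alcCutoff = alcCutoff,
                 retained = retained, targetDb = targetDb,
                 finalPsms = finalPsms, sweep = finalSweep,
                 finalThreshold = finalThr, pr = pr, misassignment = mis,
                 fdrPsmCurve = curve, features = features,
                 manifest = manifest))
}

#' Read a flat key=value configuration file
#'
#' One \code{key = value} pair per line; blank lines and lines starting with
#' \code{#} are ignored. Values are returned as character strings.
#'
#' @param path Path to the configuration file.
#' @return Named list of character values.
#' @export
readConfigFile <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- regmatches(lines, regexec("^([^=]+)=(.*)$", lines))
  bad <- lengths(kv) != 3L
  if (any(bad)) stop("malformed config line: ", lines[bad][1L])
  setNames(lapply(kv, function(x) trimws(x[3L])),
           vapply(kv, function(x) trimws(x[2L]), character(1L)))
}
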
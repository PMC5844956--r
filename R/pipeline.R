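## End-to-end orchestration: motion files + phenotypes -> speed profiles
## -> growing-window alpha samples -> bootstrap group comparisons, with a
## manifest recording inputs, parameters, seeds and exclusions.

#' Build a pipeline run configuration
#'
#' @param motionDir Directory of 6-column motion files (`<SUB_ID>.1D`).
#' @param phenotypes Path to the phenotype CSV.
#' @param outDir Output directory.
#' @param samplingRates Named numeric vector: seconds per frame by site;
#'   if `NULL`, read from a `provenance.json` sidecar next to the motion
#'   files.
#' @param comparisons List of `c(pool, reference)` label pairs (labels as
#'   in [selectGroup()]).
#' @param targetRate,nPoints,d Kinematics parameters: common rate (Hz),
#'   common length, smoothing half-width.
#' @param nMin,minPrefix DFA parameters.
#' @param nIterations Bootstrap subgroups per comparison.
#' @param ageBinWidth Width of age-matching bins in years.
#' @param poolingMode Alpha pooling mode, see [compareGroups()].
#' @param seed Master seed; all stages derive sub-seeds from it.
#' @return A `RunConfig` list.
#' @export
runConfig <- function(motionDir, phenotypes, outDir,
                      samplingRates = NULL,
                      comparisons = list(c("TD", "ASD")),
                      targetRate = 2, nPoints = 370L, d = 1L,
                      nMin = 4L, minPrefix = 40L,
                      nIterations = 500L, ageBinWidth = 2,
                      poolingMode = "subject_mean", seed = 1L) {
  cfg <- list(motionDir = motionDir, phenotypes = phenotypes,
              outDir = outDir, samplingRates = samplingRates,
              comparisons = comparisons, targetRate = targetRate,
              nPoints = as.integer(nPoints), d = as.integer(d),
              nMin = as.integer(nMin), minPrefix = as.integer(minPrefix),
              nIterations = as.integer(nIterations),
              ageBinWidth = ageBinWidth, poolingMode = poolingMode,
              seed = as.integer(seed))
  class(cfg) <- c("RunConfig", "list")
  cfg
}

validateConfig <- function(config) {
  if (!dir.exists(config$motionDir))
    invalidParameter("motion directory does not exist: %s", config$motionDir)
  if (!file.exists(config$phenotypes))
    invalidParameter("phenotype file does not exist: %s", config$phenotypes)
  for (cmp in config$comparisons) {
    if (length(cmp) != 2L || !all(cmp %in% groupLabels))
      invalidParameter("each comparison must be c(pool, reference) with labels in: %s",
                       paste(groupLabels, collapse = ", "))
  }
  if (is.null(config$samplingRates)) {
    side <- file.path(config$motionDir, "provenance.json")
    if (!file.exists(side))
      invalidParameter("samplingRates not given and no provenance.json in %s",
                       config$motionDir)
    config$samplingRates <- unlist(jsonlite::read_json(side)$samplingRates)
  }
  config
}

#' Run the full noise-signature pipeline
#'
#' Reads every subject's motion file, derives linear and angular speed
#' series (speed, triangular smoothing, resampling to the common rate,
#' truncation to the common length), estimates each subject's
#' growing-window alpha sample, and runs every configured pool-vs-reference
#' bootstrap comparison for both speed kinds. Subjects whose series are
#' too short after resampling are excluded, counted, and listed with
#' reasons in the manifest; the run continues. All outputs are tabular
#' (TSV/CSV/JSON) under `outDir`, and the manifest makes the run
#' reproducible: identical config and seed give identical tables.
#'
#' @param config A [runConfig()] list.
#' @return Invisibly, the manifest (also written as `manifest.json`):
#'   inputs, parameters, seed, per-stage record counts, exclusions with
#'   reasons, and per-comparison summary numbers.
#' @export
runPipeline <- function(config) {
  config <- validateConfig(config)
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  phen <- readPhenotypes(config$phenotypes, config$samplingRates)

  excluded <- list()
  speeds <- list(linear = list(), angular = list())
  excursions <- list()
  for (i in seq_len(nrow(phen))) {
    sid <- phen$SUB_ID[i]
    path <- file.path(config$motionDir, paste0(sid, ".1D"))
    res <- tryCatch({
      trace <- readMotionFile(path, phen$SAMPLING_INTERVAL[i], subjectId = sid)
      lin <- speedChain(trace, "linear", config$d, config$targetRate, config$nPoints)
      ang <- speedChain(trace, "angular", config$d, config$targetRate, config$nPoints)
      list(lin = lin, ang = ang)
    }, MotionNoiseError = function(e) e)
    if (inherits(res, "error")) {
      excluded[[sid]] <- conditionMessage(res)
      next
    }
    speeds$linear[[sid]] <- res$lin
    speeds$angular[[sid]] <- res$ang
    excursions[[sid]] <- pathExcursion(res$lin, res$ang)
  }
  included <- names(speeds$linear)
  if (!length(included))
    insufficientData("no subject survived the kinematics stage")
  phenIncluded <- phen[phen$SUB_ID %in% included, , drop = FALSE]

  excTab <- do.call(rbind, excursions)
  utils::write.table(excTab, file.path(config$outDir, "excursions.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)

  alphas <- list(linear = list(), angular = list())
  alphaRows <- list()
  for (kind in c("linear", "angular")) {
    for (sid in included) {
      a <- tryCatch(
        alphaSeries(speeds[[kind]][[sid]], config$minPrefix, config$nMin),
        MotionNoiseError = function(e) e)
      if (inherits(a, "error")) {
        excluded[[paste0(sid, ":", kind)]] <- conditionMessage(a)
        next
      }
      alphas[[kind]][[sid]] <- a
      alphaRows[[paste0(sid, ":", kind)]] <- data.frame(
        subjectId = sid, kind = kind, meanAlpha = a@meanAlpha,
        nAlphas = length(a@alphas), nSkipped = a@nSkipped,
        band = classifyNoise(a@meanAlpha), stringsAsFactors = FALSE)
    }
  }
  alphaTab <- do.call(rbind, alphaRows)
  utils::write.table(alphaTab, file.path(config$outDir, "alphas.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)

  comparisonSummaries <- list()
  for (kind in c("linear", "angular")) {
    haveAlpha <- names(alphas[[kind]])
    for (ci in seq_along(config$comparisons)) {
      cmp <- config$comparisons[[ci]]
      poolLab <- cmp[1L]; refLab <- cmp[2L]
      tag <- sprintf("%s_vs_%s_%s", poolLab, refLab, kind)
      pool <- selectGroup(phenIncluded, poolLab)
      reference <- selectGroup(phenIncluded, refLab)
      pool <- pool[pool$SUB_ID %in% haveAlpha, , drop = FALSE]
      reference <- reference[reference$SUB_ID %in% haveAlpha, , drop = FALSE]
      plan <- BootstrapPlan(
        nIterations = config$nIterations,
        ageBinEdges = defaultAgeBins(
          c(pool$AGE_AT_SCAN, reference$AGE_AT_SCAN), config$ageBinWidth),
        seed = subSeed(config$seed, 7000L + ci * 10L +
                         (kind == "angular")),
        referenceGroup = refLab, poolGroup = poolLab)
      report <- compareGroups(alphas[[kind]], alphas[[kind]],
                              pool, reference, plan,
                              poolingMode = config$poolingMode)
      writeComparisonReport(report, file.path(config$outDir, tag))
      refMean <- unname(gammaMoments(report@referenceFit)["mean"])
      comparisonSummaries[[tag]] <- list(
        pool = poolLab, reference = refLab, kind = kind,
        nPool = nrow(pool), nReference = nrow(reference),
        referenceMeanAlpha = refMean,
        subgroupMeanAlpha = mean(report@subgroupMeanAlphas),
        pMean = report@pMean, pMode = report@pMode,
        nOverlapping = report@nOverlapping,
        nIterations = length(report@pValues),
        fracSignificant = 1 - report@nOverlapping / length(report@pValues))
    }
  }

  manifest <- list(
    inputs = list(motionDir = config$motionDir,
                  phenotypes = config$phenotypes),
    parameters = config[c("targetRate", "nPoints", "d", "nMin", "minPrefix",
                          "nIterations", "ageBinWidth", "poolingMode")],
    seed = config$seed,
    counts = list(subjectsIn = nrow(phen),
                  subjectsIncluded = length(included),
                  subjectsExcluded = nrow(phen) - length(included)),
    exclusions = excluded,
    comparisons = comparisonSummaries)
  jsonlite::write_json(manifest, file.path(config$outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Write a comparison report as TSV + JSON summary
#'
#' @param report A [ComparisonReport].
#' @param prefix Path prefix; writes `<prefix>_subgroups.tsv` (per-subgroup
#'   Gamma parameters, mean alpha, KS D and p) and `<prefix>_summary.json`.
#' @return Invisibly, the paths written.
#' @export
writeComparisonReport <- function(report, prefix) {
  rows <- do.call(rbind, lapply(report@subgroupFits, gammaFitRow))
  rows <- cbind(subgroup = seq_len(nrow(rows)),
                meanAlpha = report@subgroupMeanAlphas,
                ksD = report@dStats, ksP = report@pValues, rows)
  tsv <- paste0(prefix, "_subgroups.tsv")
  utils::write.table(rows, tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  js <- paste0(prefix, "_summary.json")
  jsonlite::write_json(list(
    reference = gammaFitRow(report@referenceFit),
    poolingMode = report@poolingMode,
    pMean = report@pMean, pMode = report@pMode,
    nOverlapping = report@nOverlapping,
    nIterations = length(report@pValues),
    failedSubgroups = report@failedSubgroups
  ), js, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(tsv, js))
}
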
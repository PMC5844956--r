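## Central S4 containers. Motion traces and speed series are per-subject
## objects; Gamma fits and comparison reports summarize groups.

setClass("MotionTrace",
  slots = c(
    subjectId = "character",
    rotations = "matrix",
    translations = "matrix",
    samplingInterval = "numeric"
  )
)

setValidity("MotionTrace", function(object) {
  msg <- character()
  if (length(object@subjectId) != 1L) msg <- c(msg, "subjectId must be a single string")
  if (ncol(object@rotations) != 3L) msg <- c(msg, "rotations must have 3 columns (roll, pitch, yaw)")
  if (ncol(object@translations) != 3L) msg <- c(msg, "translations must have 3 columns (x, y, z)")
  if (nrow(object@rotations) != nrow(object@translations))
    msg <- c(msg, "rotations and translations must have equal frame counts")
  if (nrow(object@rotations) < 2L) msg <- c(msg, "a trace needs at least 2 frames")
  if (!all(is.finite(object@rotations)) || !all(is.finite(object@translations)))
    msg <- c(msg, "all motion parameters must be finite")
  if (length(object@samplingInterval) != 1L || !is.finite(object@samplingInterval) ||
      object@samplingInterval <= 0)
    msg <- c(msg, "samplingInterval must be a single positive number (seconds)")
  if (length(msg)) msg else TRUE
})

#' Construct a rigid-body motion trace
#'
#' A `MotionTrace` holds the six rigid-body motion parameters reported by
#' volume registration for one subject: per-frame rotations (roll, pitch,
#' yaw; degrees) and translations (x, y, z; millimetres), together with the
#' scanner's sampling interval in seconds per frame.
#'
#' @param subjectId Single subject identifier.
#' @param rotations Numeric matrix, frames x 3, rotations in degrees.
#' @param translations Numeric matrix, frames x 3, translations in mm.
#' @param samplingInterval Seconds per frame (positive).
#' @return A `MotionTrace` object.
#' @examples
#' tr <- MotionTrace("s1", matrix(0, 5, 3), matrix(rnorm(15), 5, 3), 0.5)
#' nFrames(tr)
#' @export
MotionTrace <- function(subjectId, rotations, translations, samplingInterval) {
  new("MotionTrace",
      subjectId = as.character(subjectId),
      rotations = as.matrix(rotations),
      translations = as.matrix(translations),
      samplingInterval = as.numeric(samplingInterval))
}

setClass("SpeedSeries",
  slots = c(
    subjectId = "character",
    kind = "character",
    values = "numeric",
    rate = "numeric"
  )
)

setValidity("SpeedSeries", function(object) {
  msg <- character()
  if (!object@kind %in% c("linear", "angular"))
    msg <- c(msg, "kind must be 'linear' or 'angular'")
  if (length(object@values) < 1L) msg <- c(msg, "values must be non-empty")
  if (!all(is.finite(object@values)) || any(object@values < 0))
    msg <- c(msg, "speeds must be finite and non-negative")
  if (length(object@rate) != 1L || !is.finite(object@rate) || object@rate <= 0)
    msg <- c(msg, "rate must be a single positive number (Hz)")
  if (length(msg)) msg else TRUE
})

#' Construct a speed series
#'
#' Uniformly sampled scalar speed magnitudes for one subject: linear speed
#' in mm/s or angular speed in deg/s.
#'
#' @param subjectId Subject identifier.
#' @param kind `"linear"` or `"angular"`.
#' @param values Non-negative speeds (mm/s or deg/s).
#' @param rate Sampling rate in Hz.
#' @return A `SpeedSeries` object.
#' @export
SpeedSeries <- function(subjectId, kind, values, rate) {
  new("SpeedSeries", subjectId = as.character(subjectId), kind = kind,
      values = as.numeric(values), rate = as.numeric(rate))
}

setClass("FluctuationCurve",
  slots = c(
    windowSizes = "integer",
    fluctuations = "numeric",
    alpha = "numeric",
    fitR2 = "numeric"
  )
)

setValidity("FluctuationCurve", function(object) {
  msg <- character()
  if (length(object@windowSizes) != length(object@fluctuations))
    msg <- c(msg, "windowSizes and fluctuations must have equal length")
  if (is.unsorted(object@windowSizes, strictly = TRUE))
    msg <- c(msg, "windowSizes must be strictly increasing")
  if (any(object@fluctuations < 0)) msg <- c(msg, "fluctuations must be non-negative")
  if (length(msg)) msg else TRUE
})

setClass("AlphaSample",
  slots = c(
    subjectId = "character",
    alphas = "numeric",
    meanAlpha = "numeric",
    nSkipped = "integer"
  )
)

setValidity("AlphaSample", function(object) {
  msg <- character()
  if (length(object@alphas) < 1L) msg <- c(msg, "alphas must be non-empty")
  if (!isTRUE(all.equal(object@meanAlpha, mean(object@alphas))))
    msg <- c(msg, "meanAlpha must equal the arithmetic mean of alphas")
  if (length(msg)) msg else TRUE
})

setClass("GammaFit",
  slots = c(
    shape = "numeric",
    scale = "numeric",
    ciShape = "numeric",
    ciScale = "numeric",
    logLik = "numeric",
    nObs = "integer"
  )
)

setValidity("GammaFit", function(object) {
  msg <- character()
  if (object@shape <= 0 || object@scale <= 0)
    msg <- c(msg, "shape and scale must be positive")
  if (length(object@ciShape) != 2L || length(object@ciScale) != 2L)
    msg <- c(msg, "confidence intervals must have two endpoints")
  if (length(msg)) msg else TRUE
})

setClass("BootstrapPlan",
  slots = c(
    nIterations = "integer",
    ageBinEdges = "numeric",
    seed = "integer",
    referenceGroup = "character",
    poolGroup = "character"
  )
)

setValidity("BootstrapPlan", function(object) {
  msg <- character()
  if (object@nIterations < 1L) msg <- c(msg, "nIterations must be >= 1")
  if (length(object@ageBinEdges) >= 2L && is.unsorted(object@ageBinEdges, strictly = TRUE))
    msg <- c(msg, "ageBinEdges must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' Plan for an age-matched bootstrap comparison
#'
#' Describes how a large pool group is resampled to match a smaller
#' reference group: number of bootstrap subgroups, the age-bin edges whose
#' per-bin composition each subgroup must reproduce, and the RNG seed.
#' Leave `ageBinEdges` empty to derive 2-year bins spanning both groups at
#' run time.
#'
#' @param nIterations Number of bootstrap subgroups (default 500).
#' @param ageBinEdges Strictly increasing bin edges in years, or `numeric(0)`
#'   to derive them from the data.
#' @param seed Integer RNG seed.
#' @param referenceGroup,poolGroup Group labels (see [selectGroup()]).
#' @return A `BootstrapPlan` object.
#' @export
BootstrapPlan <- function(nIterations = 500L, ageBinEdges = numeric(0),
                          seed = 1L, referenceGroup = NA_character_,
                          poolGroup = NA_character_) {
  new("BootstrapPlan", nIterations = as.integer(nIterations),
      ageBinEdges = as.numeric(ageBinEdges), seed = as.integer(seed),
      referenceGroup = referenceGroup, poolGroup = poolGroup)
}

setClass("ComparisonReport",
  slots = c(
    referenceFit = "GammaFit",
    subgroupFits = "list",
    subgroupMeanAlphas = "numeric",
    dStats = "numeric",
    pValues = "numeric",
    pMean = "numeric",
    pMode = "numeric",
    nOverlapping = "integer",
    poolingMode = "character",
    failedSubgroups = "integer"
  )
)

setValidity("ComparisonReport", function(object) {
  msg <- character()
  n <- length(object@pValues)
  if (length(object@subgroupFits) != n || length(object@subgroupMeanAlphas) != n ||
      length(object@dStats) != n)
    msg <- c(msg, "per-subgroup slots must all have length nIterations")
  if (any(object@pValues < 0 | object@pValues > 1))
    msg <- c(msg, "p-values must lie in [0, 1]")
  if (object@nOverlapping < 0L || object@nOverlapping > n)
    msg <- c(msg, "nOverlapping must lie in [0, nIterations]")
  if (length(msg)) msg else TRUE
})

setClass("CohortSpec",
  slots = c(
    groups = "list",
    sexRatio = "numeric",
    medicationRate = "numeric",
    nFrames = "integer",
    seed = "integer"
  )
)

setValidity("CohortSpec", function(object) {
  msg <- character()
  if (length(object@groups) < 1L) msg <- c(msg, "at least one group is required")
  for (g in object@groups) {
    if (g$nSubjects < 1L) msg <- c(msg, sprintf("group '%s': nSubjects must be >= 1", g$label))
    if (g$targetAlpha <= 0 || g$targetAlpha >= 2)
      msg <- c(msg, sprintf("group '%s': targetAlpha must lie in (0, 2)", g$label))
    if (g$samplingInterval <= 0)
      msg <- c(msg, sprintf("group '%s': samplingInterval must be positive", g$label))
  }
  if (object@sexRatio < 0 || object@sexRatio > 1) msg <- c(msg, "sexRatio must lie in [0, 1]")
  if (object@medicationRate < 0 || object@medicationRate > 1)
    msg <- c(msg, "medicationRate must lie in [0, 1]")
  if (object@nFrames < 2L) msg <- c(msg, "nFrames must be >= 2")
  if (length(msg)) msg else TRUE
})
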
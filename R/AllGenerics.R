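#' @name accessors
#' @title Accessors for MotionNoise objects
#' @description Slot accessors for the package's S4 containers. Use these
#'   rather than `@` access.
#' @param object A MotionNoise S4 object.
#' @return The slot value (see each generic's name).
NULL

#' @rdname accessors
#' @export
setGeneric("subjectId", function(object) standardGeneric("subjectId"))
#' @rdname accessors
#' @export
setGeneric("nFrames", function(object) standardGeneric("nFrames"))
#' @rdname accessors
#' @export
setGeneric("rotations", function(object) standardGeneric("rotations"))
#' @rdname accessors
#' @export
setGeneric("translations", function(object) standardGeneric("translations"))
#' @rdname accessors
#' @export
setGeneric("samplingInterval", function(object) standardGeneric("samplingInterval"))
#' @rdname accessors
#' @export
setGeneric("speedValues", function(object) standardGeneric("speedValues"))
#' @rdname accessors
#' @export
setGeneric("sampleRate", function(object) standardGeneric("sampleRate"))
#' @rdname accessors
#' @export
setGeneric("seriesKind", function(object) standardGeneric("seriesKind"))
#' @rdname accessors
#' @export
setGeneric("alphaValues", function(object) standardGeneric("alphaValues"))
#' @rdname accessors
#' @export
setGeneric("meanAlpha", function(object) standardGeneric("meanAlpha"))
#' @rdname accessors
#' @export
setGeneric("scalingAlpha", function(object) standardGeneric("scalingAlpha"))
#' @rdname accessors
#' @export
setGeneric("windowSizes", function(object) standardGeneric("windowSizes"))
#' @rdname accessors
#' @export
setGeneric("fluctuations", function(object) standardGeneric("fluctuations"))
#' @rdname accessors
#' @export
setGeneric("gammaShape", function(object) standardGeneric("gammaShape"))
#' @rdname accessors
#' @export
setGeneric("gammaScale", function(object) standardGeneric("gammaScale"))
#' @rdname accessors
#' @export
setGeneric("gammaCI", function(object) standardGeneric("gammaCI"))
#' @rdname accessors
#' @export
setGeneric("gammaMoments", function(object) standardGeneric("gammaMoments"))
#' @rdname accessors
#' @export
setGeneric("gammaNSR", function(object) standardGeneric("gammaNSR"))
#' @rdname accessors
#' @export
setGeneric("pValues", function(object) standardGeneric("pValues"))
#' @rdname accessors
#' @export
setGeneric("referenceFit", function(object) standardGeneric("referenceFit"))
#' @rdname accessors
#' @export
setGeneric("subgroupFits", function(object) standardGeneric("subgroupFits"))
#' @rdname accessors
#' @export
setGeneric("nOverlapping", function(object) standardGeneric("nOverlapping"))

setMethod("subjectId", "MotionTrace", function(object) object@subjectId)
setMethod("subjectId", "SpeedSeries", function(object) object@subjectId)
setMethod("subjectId", "AlphaSample", function(object) object@subjectId)
setMethod("nFrames", "MotionTrace", function(object) nrow(object@rotations))
setMethod("rotations", "MotionTrace", function(object) object@rotations)
setMethod("translations", "MotionTrace", function(object) object@translations)
setMethod("samplingInterval", "MotionTrace", function(object) object@samplingInterval)
setMethod("speedValues", "SpeedSeries", function(object) object@values)
setMethod("sampleRate", "SpeedSeries", function(object) object@rate)
setMethod("seriesKind", "SpeedSeries", function(object) object@kind)
setMethod("alphaValues", "AlphaSample", function(object) object@alphas)
setMethod("meanAlpha", "AlphaSample", function(object) object@meanAlpha)
setMethod("scalingAlpha", "FluctuationCurve", function(object) object@alpha)
setMethod("windowSizes", "FluctuationCurve", function(object) object@windowSizes)
setMethod("fluctuations", "FluctuationCurve", function(object) object@fluctuations)
setMethod("gammaShape", "GammaFit", function(object) object@shape)
setMethod("gammaScale", "GammaFit", function(object) object@scale)
setMethod("gammaCI", "GammaFit", function(object)
  list(shape = object@ciShape, scale = object@ciScale))

## Gamma moments are derived from (shape, scale) so the moment identities
## mean = a*b, var = a*b^2, skew = 2/sqrt(a), excess kurtosis = 6/a hold
## exactly for every fit.
setMethod("gammaMoments", "GammaFit", function(object) {
  a <- object@shape; b <- object@scale
  c(mean = a * b, variance = a * b^2, skewness = 2 / sqrt(a),
    kurtosis = 3 + 6 / a, excessKurtosis = 6 / a)
})

setMethod("pValues", "ComparisonReport", function(object) object@pValues)
setMethod("referenceFit", "ComparisonReport", function(object) object@referenceFit)
setMethod("subgroupFits", "ComparisonReport", function(object) object@subgroupFits)
setMethod("nOverlapping", "ComparisonReport", function(object) object@nOverlapping)

setMethod("show", "MotionTrace", function(object) {
  cat(sprintf("MotionTrace '%s': %d frames @ %.4g s/frame (%.3g Hz)\n",
              object@subjectId, nrow(object@rotations), object@samplingInterval,
              1 / object@samplingInterval))
})

setMethod("show", "SpeedSeries", function(object) {
  cat(sprintf("SpeedSeries '%s' (%s): %d points @ %.3g Hz, mean %.4g %s\n",
              object@subjectId, object@kind, length(object@values), object@rate,
              mean(object@values),
              if (object@kind == "linear") "mm/s" else "deg/s"))
})

setMethod("show", "FluctuationCurve", function(object) {
  cat(sprintf("FluctuationCurve: %d window sizes in [%d, %d], alpha = %.4f (R2 = %.3f)\n",
              length(object@windowSizes), min(object@windowSizes),
              max(object@windowSizes), object@alpha, object@fitR2))
})

setMethod("show", "AlphaSample", function(object) {
  cat(sprintf("AlphaSample '%s': %d growing-window alphas, mean %.4f (%d prefixes skipped)\n",
              object@subjectId, length(object@alphas), object@meanAlpha, object@nSkipped))
})

setMethod("show", "GammaFit", function(object) {
  m <- gammaMoments(object)
  cat(sprintf(paste0(
    "GammaFit (n = %d): shape %.4g [%.4g, %.4g], scale %.4g [%.4g, %.4g]\n",
    "  mean %.4g  var %.4g  skew %.4g  excess kurtosis %.4g  NSR %.4g\n"),
    object@nObs, object@shape, object@ciShape[1], object@ciShape[2],
    object@scale, object@ciScale[1], object@ciScale[2],
    m["mean"], m["variance"], m["skewness"], m["excessKurtosis"], object@scale))
})

setMethod("show", "ComparisonReport", function(object) {
  cat(sprintf(paste0(
    "ComparisonReport: %d bootstrap subgroups (%s pooling)\n",
    "  reference alpha mean %.4f; subgroup alpha means in [%.4f, %.4f]\n",
    "  KS p-values: mean %.3g, mode %.3g; %d/%d subgroups with p >= 0.05\n"),
    length(object@pValues), object@poolingMode,
    gammaMoments(object@referenceFit)["mean"],
    min(object@subgroupMeanAlphas), max(object@subgroupMeanAlphas),
    object@pMean, object@pMode, object@nOverlapping, length(object@pValues)))
})

setMethod("show", "CohortSpec", function(object) {
  cat(sprintf("CohortSpec: %d groups, %d frames/subject, seed %d\n",
              length(object@groups), object@nFrames, object@seed))
  for (g in object@groups)
    cat(sprintf("  %s: n = %d, target alpha %.2f, interval %.3g s\n",
                g$label, g$nSubjects, g$targetAlpha, g$samplingInterval))
})

#' @exportMethod show
setMethod("show", "BootstrapPlan", function(object) {
  cat(sprintf("BootstrapPlan: %d iterations, %s -> %s, seed %d\n",
              object@nIterations, object@poolGroup, object@referenceGroup,
              object@seed))
})
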
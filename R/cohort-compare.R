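## Age-matched bootstrap subgrouping, two-sample KS comparison of alpha
## distributions, and the alpha noise-band taxonomy.

defaultAgeBins <- function(ages, width = 2) {
  lo <- floor(min(ages) / width) * width
  hi <- ceiling(max(ages) / width) * width
  if (hi <= lo) hi <- lo + width
  seq(lo, hi, by = width)
}

binAges <- function(ages, edges) {
  cut(ages, breaks = edges, include.lowest = TRUE, right = FALSE)
}

#' Age-matched bootstrap subgroups
#'
#' Draws `nIterations` subgroups from `pool`, each reproducing the
#' reference group's age-bin composition exactly: for every age bin the
#' subgroup contains exactly as many pool subjects (sampled with
#' replacement, within the bin) as the reference has. Every subgroup
#' therefore has exactly the reference's size. Bins where the reference
#' has subjects but the pool has none make the matching infeasible and
#' raise an error naming the bin.
#'
#' @param pool Data.frame of subject records (the larger group).
#' @param reference Data.frame of subject records (the smaller group whose
#'   size and age composition are to be matched).
#' @param plan A [BootstrapPlan()]. Empty `ageBinEdges` derive 2-year bins
#'   spanning both groups.
#' @return List of `nIterations` data.frames, each a subgroup of `pool`
#'   rows.
#' @export
ageMatchedBootstrap <- function(pool, reference, plan) {
  validObject(plan)
  if (nrow(pool) < 1L || nrow(reference) < 1L)
    insufficientData("pool and reference must both be non-empty")
  edges <- plan@ageBinEdges
  if (length(edges) < 2L)
    edges <- defaultAgeBins(c(pool$AGE_AT_SCAN, reference$AGE_AT_SCAN))
  if (min(edges) > min(c(pool$AGE_AT_SCAN, reference$AGE_AT_SCAN)) ||
      max(edges) < max(c(pool$AGE_AT_SCAN, reference$AGE_AT_SCAN)))
    invalidParameter("ageBinEdges [%g, %g] do not cover both groups' age ranges",
                     min(edges), max(edges))
  refBins <- binAges(reference$AGE_AT_SCAN, edges)
  poolBins <- binAges(pool$AGE_AT_SCAN, edges)
  refCounts <- table(refBins)
  usedBins <- names(refCounts)[refCounts > 0]
  for (b in usedBins) {
    if (sum(poolBins == b) == 0L)
      matchingInfeasible("age bin %s has %d reference subject(s) but no pool subjects",
                         b, refCounts[[b]])
  }
  poolIdxByBin <- lapply(usedBins, function(b) which(poolBins == b))
  names(poolIdxByBin) <- usedBins
  withSeed(plan@seed, {
    lapply(seq_len(plan@nIterations), function(it) {
      idx <- unlist(lapply(usedBins, function(b) {
        cand <- poolIdxByBin[[b]]
        cand[sample.int(length(cand), refCounts[[b]], replace = TRUE)]
      }), use.names = FALSE)
      pool[idx, , drop = FALSE]
    })
  })
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' `D` is the supremum distance between the two empirical CDFs; the
#' p-value uses the asymptotic two-sample KS distribution.
#'
#' @param a,b Non-empty numeric samples.
#' @return List with elements `D` and `p`.
#' @export
ksTwoSample <- function(a, b) {
  if (!length(a) || !length(b))
    insufficientData("both samples must be non-empty")
  kt <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
  list(D = unname(kt$statistic), p = unname(kt$p.value))
}

## Reduce a named list of AlphaSample objects to one numeric sample per
## pooling mode: "subject_mean" takes each subject's mean alpha (one value
## per subject, exchangeable across subjects); "pooled" concatenates every
## subject's full growing-window alpha series.
poolAlphas <- function(alphaSamples, ids, poolingMode) {
  found <- ids %in% names(alphaSamples)
  if (!all(found))
    lookupError("no alpha sample for subject(s): %s",
                paste(head(ids[!found], 5L), collapse = ", "))
  if (poolingMode == "subject_mean")
    vapply(ids, function(i) alphaSamples[[i]]@meanAlpha, numeric(1))
  else
    unlist(lapply(ids, function(i) alphaSamples[[i]]@alphas), use.names = FALSE)
}

logHistMode <- function(p, nBins = 20L) {
  lp <- log2(pmax(p, .Machine$double.xmin))
  h <- graphics::hist(lp, breaks = nBins, plot = FALSE)
  2^h$mids[which.max(h$counts)]
}

#' Bootstrap group comparison of alpha distributions
#'
#' For each age-matched bootstrap subgroup of the pool, collects an alpha
#' sample (per `poolingMode`), fits a Gamma distribution by MLE, and runs
#' a two-sample KS test against the reference group's alpha sample. The
#' report carries the reference fit, all subgroup fits, subgroup mean
#' alphas, the p-value distribution with its mean and mode (mode from the
#' tallest bin of a histogram on log2-transformed p-values), and the count
#' of subgroups with p >= 0.05 ("overlapping" with the reference).
#'
#' Pooling modes: `"subject_mean"` (default) represents each subject by
#' the mean of its growing-window alpha series, keeping observations
#' exchangeable so KS p-values are calibrated under the null;
#' `"pooled"` concatenates all growing-window alphas of a group, which
#' gives the Gamma fit many observations but makes the KS test
#' anti-conservative because within-subject alphas are strongly
#' dependent.
#'
#' @param poolAlphasBySubject,referenceAlphasBySubject Named lists of
#'   [AlphaSample] objects, keyed by subject id.
#' @param pool,reference Subject-record data.frames (rows with `SUB_ID`
#'   and `AGE_AT_SCAN`) for the two groups.
#' @param plan A [BootstrapPlan()].
#' @param poolingMode `"subject_mean"` or `"pooled"`.
#' @param alphaLevel Significance threshold for the overlap count.
#' @return A [ComparisonReport].
#' @export
compareGroups <- function(poolAlphasBySubject, referenceAlphasBySubject,
                          pool, reference, plan,
                          poolingMode = c("subject_mean", "pooled"),
                          alphaLevel = 0.05) {
  poolingMode <- match.arg(poolingMode)
  refSample <- poolAlphas(referenceAlphasBySubject, reference$SUB_ID, poolingMode)
  refFit <- fitGammaMLE(refSample)
  subgroups <- ageMatchedBootstrap(pool, reference, plan)
  nIt <- length(subgroups)
  fits <- vector("list", nIt)
  means <- rep(NA_real_, nIt)
  ds <- rep(NA_real_, nIt)
  ps <- rep(NA_real_, nIt)
  failed <- integer(0)
  for (it in seq_len(nIt)) {
    res <- tryCatch({
      sg <- poolAlphas(poolAlphasBySubject, subgroups[[it]]$SUB_ID, poolingMode)
      fit <- fitGammaMLE(sg)
      kt <- ksTwoSample(sg, refSample)
      list(fit = fit, mean = mean(sg), D = kt$D, p = kt$p)
    }, MotionNoiseError = function(e) e)
    if (inherits(res, "error")) {
      failed <- c(failed, it)
      next
    }
    fits[[it]] <- res$fit
    means[it] <- res$mean
    ds[it] <- res$D
    ps[it] <- res$p
  }
  if (length(failed) > 0.1 * nIt)
    degenerateData("more than 10%% of bootstrap subgroups failed (%d of %d; first failures: %s)",
                   length(failed), nIt, paste(head(failed, 5L), collapse = ", "))
  ok <- !is.na(ps)
  new("ComparisonReport",
      referenceFit = refFit,
      subgroupFits = fits[ok],
      subgroupMeanAlphas = means[ok],
      dStats = ds[ok],
      pValues = ps[ok],
      pMean = mean(ps[ok]),
      pMode = logHistMode(ps[ok]),
      nOverlapping = sum(ps[ok] >= alphaLevel),
      poolingMode = poolingMode,
      failedSubgroups = as.integer(failed))
}

#' Classify a scaling exponent into a noise band
#'
#' Maps a DFA exponent onto the standard taxonomy of random processes:
#' anti-persistent fGn below 0.5, white noise near 0.5, persistent fGn in
#' (0.5, 1], pink (1/f) noise near 1, anti-persistent fBm in (1, 1.5),
#' brown noise near 1.5, persistent fBm above 1.5. "Near" means within
#' `tolerance` of the landmark value; outside the tolerance the interval
#' labels apply.
#'
#' @param alpha Finite positive scaling exponent(s).
#' @param tolerance Half-width of the landmark bands (default 0.05).
#' @return Character vector of band labels.
#' @examples
#' classifyNoise(c(0.3, 0.5, 0.8, 1.0, 1.2, 1.5, 1.66, 1.73))
#' @export
classifyNoise <- function(alpha, tolerance = 0.05) {
  if (any(!is.finite(alpha)) || any(alpha <= 0))
    domainError("alpha must be finite and positive")
  vapply(alpha, function(a) {
    if (abs(a - 0.5) <= tolerance) "white noise"
    else if (abs(a - 1.0) <= tolerance) "pink noise"
    else if (abs(a - 1.5) <= tolerance) "brown noise"
    else if (a < 0.5) "anti-persistent fGn"
    else if (a <= 1.0) "persistent fGn"
    else if (a < 1.5) "anti-persistent fBm"
    else "persistent fBm"
  }, character(1))
}
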
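## Detrended Fluctuation Analysis.
##
## Profile -> windowed linear detrending -> RMS fluctuation F(n) ->
## log-log slope alpha. The growing-window variant re-estimates alpha on
## every prefix of the series, giving a per-subject sample of alphas.

## Least-squares linear detrending of all K windows at once, in closed
## form: for window k with points X_k over t = 1..n, the fitted line is
## mean(X_k) + slope_k * (t - mean(t)); residual sums need only O(n K)
## work, which keeps the growing-window analysis fast.
windowResiduals <- function(X) {
  n <- nrow(X)
  tc <- seq_len(n) - (n + 1) / 2
  slopes <- crossprod(tc, X) / sum(tc * tc)     # 1 x K
  X - rep(colMeans(X), each = n) - tcrossprod(tc, slopes[1L, ])
}

#' Cumulative (mean-centered) profile of a series
#'
#' `profile[t] = sum_{i<=t} (x_i - mean(x))`; the final element is zero up
#' to rounding, and the profile converts a bounded series into an
#' unbounded random-walk-like process suitable for fluctuation analysis.
#'
#' @param x Numeric series (or [SpeedSeries]) of length >= 2.
#' @return Numeric vector of the same length.
#' @examples
#' cumulativeProfile(c(1, 2, 3))  # -1, -1, 0
#' @export
cumulativeProfile <- function(x) {
  if (is(x, "SpeedSeries")) x <- x@values
  if (length(x) < 2L)
    insufficientData("profile needs at least 2 points, got %d", length(x))
  cumsum(x - mean(x))
}

#' RMS fluctuation around piecewise-linear trends
#'
#' Divides the profile into the leading `floor(N / n)` non-overlapping
#' windows of length `n`, fits a least-squares line in each, and returns
#' the root-mean-square residual over all points inside complete windows.
#' The trailing remainder (fewer than `n` points) is discarded.
#'
#' @param profile Cumulative profile from [cumulativeProfile()].
#' @param n Window size; must satisfy `4 <= n <= floor(N / 10)` unless
#'   `strict = FALSE`.
#' @param strict Enforce the `n <= N/10` upper bound (default `TRUE`).
#' @return `F(n) >= 0`.
#' @export
dfaFluctuation <- function(profile, n, strict = TRUE) {
  N <- length(profile)
  n <- as.integer(n)
  if (n < 4L || (strict && n > N %/% 10L) || n > N %/% 2L)
    invalidParameter("window size n = %d outside the admissible range [4, %d] for N = %d",
                     n, if (strict) N %/% 10L else N %/% 2L, N)
  K <- N %/% n
  X <- matrix(profile[seq_len(n * K)], n, K)
  R <- windowResiduals(X)
  sqrt(sum(R * R) / (n * K))
}

#' DFA scaling exponent of a series
#'
#' Computes the fluctuation function over every integer window size in
#' `[nMin, nMax]` and returns the least-squares slope of `log F(n)` versus
#' `log n`, the scaling exponent alpha: 0.5 for white noise, 1 for pink
#' (1/f) noise, 1.5 for brown noise (integrated white noise); more
#' generally alpha = H for fGn and H + 1 for fBm with Hurst exponent H.
#'
#' @param x Numeric series or [SpeedSeries]; length >= 40 under the
#'   default `nMax`.
#' @param nMin Smallest window size (default 4).
#' @param nMax Largest window size; default `floor(N / 10)`. At least two
#'   window sizes with positive fluctuation are required for a slope.
#' @return A [FluctuationCurve] with the window sizes, `F(n)`, alpha and
#'   the R-squared of the log-log fit.
#' @examples
#' set.seed(1)
#' scalingAlpha(dfaAlpha(rnorm(2048)))          # about 0.5
#' scalingAlpha(dfaAlpha(cumsum(rnorm(2048))))  # about 1.5
#' @export
dfaAlpha <- function(x, nMin = 4L, nMax = NULL) {
  if (is(x, "SpeedSeries")) x <- x@values
  N <- length(x)
  if (is.null(nMax)) nMax <- N %/% 10L
  nMin <- as.integer(nMin); nMax <- as.integer(nMax)
  if (nMax > N %/% 2L) nMax <- N %/% 2L
  if (nMin < 4L || nMax < nMin + 1L)
    insufficientData("series of length %d admits window sizes [%d, %d]; need at least two sizes >= 4",
                     N, nMin, nMax)
  prof <- cumulativeProfile(x)
  ns <- nMin:nMax
  Fs <- vapply(ns, function(n) dfaFluctuation(prof, n, strict = FALSE),
               numeric(1))
  ok <- Fs > 0
  if (sum(ok) < 2L)
    degenerateSignal("all fluctuations vanish (constant or linear-in-time input); alpha undefined")
  ln <- log(ns[ok]); lf <- log(Fs[ok])
  slope <- cov(ln, lf) / var(ln)
  r2 <- cov(ln, lf)^2 / (var(ln) * var(lf))
  new("FluctuationCurve", windowSizes = ns, fluctuations = Fs,
      alpha = slope, fitR2 = r2)
}

#' Growing-window alpha series for one subject
#'
#' Re-estimates the DFA exponent on every prefix of the series, from
#' `minPrefix` points up to the full length, yielding a per-subject sample
#' of alpha values whose arithmetic mean summarizes the subject. For
#' prefixes too short for two window sizes under the `n <= N/10` rule
#' (lengths below 50), the largest window is relaxed minimally to
#' `nMin + 1` so that a slope exists; prefixes whose fluctuations all
#' vanish are skipped and counted.
#'
#' @param x Numeric series or [SpeedSeries].
#' @param minPrefix Shortest prefix length (default 40).
#' @param nMin Smallest DFA window size (default 4).
#' @param subjectId Identifier recorded in the result.
#' @return An [AlphaSample].
#' @export
alphaSeries <- function(x, minPrefix = 40L, nMin = 4L, subjectId = NULL) {
  if (is.null(subjectId))
    subjectId <- if (is(x, "SpeedSeries")) x@subjectId else "series"
  if (is(x, "SpeedSeries")) x <- x@values
  N <- length(x)
  if (N < minPrefix)
    insufficientData("series of length %d is shorter than minPrefix = %d", N, minPrefix)
  alphas <- rep(NA_real_, N - minPrefix + 1L)
  for (L in minPrefix:N) {
    nMax <- max(L %/% 10L, nMin + 1L)
    ## prefix profile must be re-centered on the prefix mean
    px <- x[seq_len(L)]
    a <- tryCatch(dfaAlpha(px, nMin, nMax)@alpha,
                  degenerateSignalError = function(e) NA_real_)
    alphas[L - minPrefix + 1L] <- a
  }
  skipped <- sum(is.na(alphas))
  alphas <- alphas[!is.na(alphas)]
  if (!length(alphas))
    degenerateSignal("no prefix of '%s' admits a DFA slope", subjectId)
  new("AlphaSample", subjectId = subjectId, alphas = alphas,
      meanAlpha = mean(alphas), nSkipped = as.integer(skipped))
}
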
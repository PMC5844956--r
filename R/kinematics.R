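## From rigid-body motion parameters to uniformly sampled speed profiles.
##
## Processing order for the standard chain: speed -> triangular smoothing
## -> antialiased resampling to a common rate -> truncation to a common
## length. Each step is exposed separately.

#' Frame-to-frame scalar speed of a motion trace
#'
#' The Euclidean norm of the per-frame displacement of the chosen channel
#' triplet, divided by the sampling interval: for the linear kind,
#' `sqrt(dx^2 + dy^2 + dz^2) / dt` in mm/s; for the angular kind the same
#' norm over the (roll, pitch, yaw) increments in deg/s. A per-frame mode
#' (no division by the interval, i.e. displacement per frame) is available
#' for rate-free comparisons.
#'
#' @param trace A [MotionTrace].
#' @param kind `"linear"` (translations) or `"angular"` (rotations).
#' @param perSecond If `FALSE`, report displacement per frame instead of
#'   per second.
#' @return A [SpeedSeries] of length `nFrames(trace) - 1`.
#' @examples
#' tr <- MotionTrace("s", matrix(0, 4, 3),
#'                   cbind(c(0, 3, 6, 9), c(0, 4, 8, 12), 0), 1)
#' speedValues(computeSpeed(tr, "linear"))  # 3-4-5 triangle: 5 mm/s
#' @export
computeSpeed <- function(trace, kind = c("linear", "angular"),
                         perSecond = TRUE) {
  kind <- match.arg(kind)
  if (nFrames(trace) < 2L)
    insufficientData("speed needs at least 2 frames, got %d", nFrames(trace))
  chan <- if (kind == "linear") trace@translations else trace@rotations
  d <- diff(chan)
  s <- sqrt(rowSums(d^2))
  if (perSecond) s <- s / trace@samplingInterval
  SpeedSeries(trace@subjectId, kind, s,
              rate = 1 / trace@samplingInterval)
}

triangularWeights <- function(d) (d + 1) - abs(seq(-d, d))

#' Triangular-window smoothing
#'
#' Symmetric weighted moving average with triangular weights
#' `d + 1 - |k|` for `k` in `[-d, d]`, normalized by their sum. At the
#' series boundaries the window is truncated and the remaining weights
#' renormalized, so constants are preserved everywhere and the output
#' length equals the input length. `d = 0` is the identity.
#'
#' @param series A [SpeedSeries] (or bare numeric vector).
#' @param d Half-width of the window, integer >= 0; the window spans
#'   `2 d + 1` points.
#' @return Smoothed series of the same class and length.
#' @export
triangularSmooth <- function(series, d = 1L) {
  if (!isCount(d + 1) || d < 0)
    invalidParameter("d must be a non-negative integer, got %s", format(d))
  x <- if (is(series, "SpeedSeries")) series@values else as.numeric(series)
  n <- length(x)
  if (n <= 2 * d)
    invalidParameter("series length %d must exceed 2 d = %d", n, 2 * d)
  if (d == 0) return(series)
  w <- triangularWeights(d)
  num <- stats::convolve(x, rev(w), type = "open")[(d + 1):(d + n)]
  den <- stats::convolve(rep(1, n), rev(w), type = "open")[(d + 1):(d + n)]
  out <- num / den
  out <- pmax(out, 0)              # guard tiny negative rounding residue
  if (is(series, "SpeedSeries"))
    SpeedSeries(series@subjectId, series@kind, out, series@rate)
  else out
}

## Windowed-sinc FIR low-pass, Kaiser beta = 5, 10 zero crossings per
## side -- the standard polyphase antialiasing design.
resampleFIR <- function(p, q) {
  pqmax <- max(p, q)
  L <- 2L * 10L * pqmax + 1L
  h <- signal::fir1(L - 1L, 1 / pqmax, window = signal::kaiser(L, 5))
  p * h / sum(h)
}

#' Antialiased rational-rate resampling
#'
#' Resamples a uniformly sampled series at `P/Q` times its original rate,
#' where `P/Q` is a bounded rational approximation of
#' `targetRate / rate(series)`. The series is upsampled by zero-stuffing,
#' filtered with an antialiasing FIR low-pass (windowed-sinc, Kaiser
#' window), and decimated; the filter's group delay is compensated so the
#' output is aligned with the input (zero-phase). Edges are padded by
#' sample replication before filtering, so constants are preserved up to
#' the filter's passband ripple; a transient of about one filter
#' half-length can remain near the edges for non-constant signals.
#'
#' @param series A [SpeedSeries].
#' @param targetRate Desired output rate in Hz (> 0).
#' @param maxDenominator Bound on `Q` in the rational approximation.
#' @return A [SpeedSeries] at `targetRate` with
#'   `ceiling(n * P / Q)` points.
#' @export
resampleUniform <- function(series, targetRate = 2, maxDenominator = 1000L) {
  if (!isScalar(targetRate) || targetRate <= 0)
    invalidParameter("targetRate must be positive, got %s", format(targetRate))
  pq <- rationalApprox(targetRate / series@rate, maxDenominator)
  p <- pq[["p"]]; q <- pq[["q"]]
  x <- series@values
  n <- length(x)
  if (p == q)
    return(SpeedSeries(series@subjectId, series@kind, x, targetRate))
  h <- resampleFIR(p, q)
  L <- length(h)
  npad <- ceiling(L / p)
  if (n <= npad)
    insufficientData("series of length %d is shorter than the filter half-length %d",
                     n, npad)
  xp <- c(rep(x[1L], npad), x, rep(x[n], npad))
  np <- length(xp)
  v <- numeric(np * p)
  v[seq(1L, by = p, length.out = np)] <- xp
  yy <- stats::convolve(v, rev(h), type = "open")
  delay <- (L - 1L) / 2 + npad * p
  m <- ceiling(n * p / q)
  idx <- delay + 1 + (seq_len(m) - 1L) * q
  out <- pmax(yy[idx], 0)          # speeds are non-negative by definition
  SpeedSeries(series@subjectId, series@kind, out, targetRate)
}

#' Truncate a speed series to a fixed length
#'
#' Keeps the first `n` points. Series shorter than `n` raise an
#' insufficient-data error so that callers can flag the subject for
#' exclusion; nothing is padded silently.
#'
#' @param series A [SpeedSeries].
#' @param n Target length (default 370, the common length used for
#'   cross-subject comparison).
#' @return A [SpeedSeries] of length exactly `n`.
#' @export
truncateSeries <- function(series, n = 370L) {
  if (!isCount(n)) invalidParameter("n must be a positive integer")
  len <- length(series@values)
  if (len < n)
    insufficientData("series '%s' has %d points, fewer than the required %d",
                     series@subjectId, len, n)
  SpeedSeries(series@subjectId, series@kind, series@values[seq_len(n)],
              series@rate)
}

#' Head-excursion summary
#'
#' Sums the speed profiles into path lengths (speed times the sampling
#' step, accumulated: mm for linear, degrees for angular) and reports mean
#' speeds. Both series must belong to the same subject and have the same
#' length.
#'
#' @param linear Linear [SpeedSeries] (mm/s).
#' @param angular Angular [SpeedSeries] (deg/s).
#' @return One-row data.frame: `subjectId`, `linearPath` (mm),
#'   `angularPath` (deg), `linearMeanSpeed` (mm/s), `angularMeanSpeed`
#'   (deg/s).
#' @export
pathExcursion <- function(linear, angular) {
  if (linear@subjectId != angular@subjectId)
    invalidParameter("speed series belong to different subjects ('%s' vs '%s')",
                     linear@subjectId, angular@subjectId)
  if (length(linear@values) != length(angular@values))
    invalidParameter("speed series lengths differ (%d vs %d)",
                     length(linear@values), length(angular@values))
  if (linear@kind != "linear" || angular@kind != "angular")
    invalidParameter("expected one linear and one angular series")
  data.frame(
    subjectId = linear@subjectId,
    linearPath = sum(linear@values) / linear@rate,
    angularPath = sum(angular@values) / angular@rate,
    linearMeanSpeed = mean(linear@values),
    angularMeanSpeed = mean(angular@values),
    stringsAsFactors = FALSE)
}

#' Standard kinematics chain for one trace
#'
#' Convenience wrapper applying [computeSpeed()], [triangularSmooth()],
#' [resampleUniform()] and [truncateSeries()] in that order.
#'
#' @param trace A [MotionTrace].
#' @param kind `"linear"` or `"angular"`.
#' @param d Triangular smoothing half-width.
#' @param targetRate Common output rate in Hz.
#' @param nPoints Common output length.
#' @return A [SpeedSeries] of length `nPoints` at `targetRate`.
#' @export
speedChain <- function(trace, kind = c("linear", "angular"), d = 1L,
                       targetRate = 2, nPoints = 370L) {
  kind <- match.arg(kind)
  s <- computeSpeed(trace, kind)
  s <- triangularSmooth(s, d)
  s <- resampleUniform(s, targetRate)
  truncateSeries(s, nPoints)
}
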
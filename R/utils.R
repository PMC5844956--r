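#' @importFrom methods new validObject is slot show
#' @importFrom stats rnorm runif fft var cov sd qnorm ks.test
#'   dgamma dlnorm dnorm dexp convolve
#' @importFrom graphics hist
#' @importFrom utils read.table write.table head tail
NULL

## Classed error conditions so callers can distinguish failure modes
## programmatically (tests match on these classes).
stopc <- function(class, fmt, ...) {
  msg <- sprintf(fmt, ...)
  stop(structure(
    class = c(class, "MotionNoiseError", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

invalidParameter <- function(fmt, ...) stopc("invalidParameterError", fmt, ...)
insufficientData <- function(fmt, ...) stopc("insufficientDataError", fmt, ...)
formatError      <- function(fmt, ...) stopc("formatError", fmt, ...)
degenerateSignal <- function(fmt, ...) stopc("degenerateSignalError", fmt, ...)
degenerateData   <- function(fmt, ...) stopc("degenerateDataError", fmt, ...)
domainError      <- function(fmt, ...) stopc("domainError", fmt, ...)
lookupError      <- function(fmt, ...) stopc("lookupError", fmt, ...)
matchingInfeasible <- function(fmt, ...) stopc("matchingInfeasibleError", fmt, ...)

## Evaluate `expr` under a fixed RNG seed without disturbing the caller's
## RNG state. All randomness in the package flows through this helper.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

## Deterministic sub-seed streams: a master seed spawns per-channel and
## per-subject seeds. Arithmetic in doubles (exact below 2^53), result
## kept inside the 32-bit signed range R's set.seed() accepts.
subSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(k) * 1013 + 17) %% 2147483629)
}

## Bounded continued-fraction rational approximation of a positive real,
## used to express a resampling ratio as P/Q.
rationalApprox <- function(x, max_denom = 1000L, tol = 1e-9) {
  if (!is.finite(x) || x <= 0)
    invalidParameter("rational approximation requires a positive finite ratio, got %s", format(x))
  p0 <- 0; q0 <- 1; p1 <- 1; q1 <- 0
  r <- x
  repeat {
    a <- floor(r)
    p2 <- a * p1 + p0; q2 <- a * q1 + q0
    if (q2 > max_denom) break
    p0 <- p1; q0 <- q1; p1 <- p2; q1 <- q2
    if (abs(p1 / q1 - x) < tol * x) break
    frac <- r - a
    if (frac < 1e-12) break
    r <- 1 / frac
  }
  c(p = as.integer(p1), q = as.integer(q1))
}

isCount <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 1 && x == floor(x)
isScalar <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x)
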
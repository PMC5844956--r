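## Colored-noise synthesis and the synthetic multi-site cohort generator.
##
## The generator exists so that every downstream stage (kinematics, DFA,
## Gamma fitting, bootstrap comparison) can be validated against series of
## known scaling exponent: DFA alpha = H for fractional Gaussian noise
## (fGn) and H + 1 for fractional Brownian motion (fBm).

#' Exact autocovariance of fractional Gaussian noise
#'
#' gamma(k) = (|k+1|^2H - 2|k|^2H + |k-1|^2H) / 2 for unit-variance fGn.
#'
#' @param hurst Hurst exponent in (0, 1).
#' @param lags Non-negative integer lags.
#' @return Autocovariance values at `lags`.
#' @export
fgnAutocovariance <- function(hurst, lags) {
  if (!isScalar(hurst) || hurst <= 0 || hurst >= 1)
    invalidParameter("hurst must lie strictly in (0, 1), got %s", format(hurst))
  k <- abs(lags)
  0.5 * (abs(k + 1)^(2 * hurst) - 2 * k^(2 * hurst) + abs(k - 1)^(2 * hurst))
}

checkNoiseSpec <- function(hurst, n) {
  if (!isScalar(hurst) || hurst <= 0 || hurst >= 1)
    invalidParameter("hurst must lie strictly in (0, 1), got %s", format(hurst))
  if (!isCount(n) || n < 2)
    invalidParameter("n must be an integer >= 2, got %s", format(n))
}

#' Simulate fractional Gaussian noise
#'
#' Exact simulation by circulant embedding (Davies-Harte): the target fGn
#' autocovariance is embedded in a circulant matrix whose eigenvalues are
#' obtained by FFT; a complex Gaussian vector is colored in the frequency
#' domain. For Hurst exponents in (0, 1) the embedding is non-negative
#' definite, so the sample path has exactly the fGn covariance. Should a
#' numerically negative eigenvalue beyond rounding error ever arise, the
#' spectrum is truncated at zero and a warning records the approximation.
#'
#' @param n Number of points (>= 2).
#' @param hurst Hurst exponent in (0, 1); `hurst = 0.5` gives white noise.
#' @param seed Integer seed; the same seed reproduces the series exactly.
#' @return Numeric vector of length `n`, zero mean and unit variance in
#'   expectation.
#' @examples
#' x <- generateFGn(1024, hurst = 0.8, seed = 1)
#' @seealso [generateFBm()], [fgnAutocovariance()]
#' @export
generateFGn <- function(n, hurst, seed = NULL) {
  checkNoiseSpec(hurst, n)
  n <- as.integer(n)
  g <- fgnAutocovariance(hurst, 0:n)
  circ <- c(g, g[n:2])                      # first row of the 2n circulant
  lam <- Re(fft(circ))
  neg <- lam < 0
  if (any(neg)) {
    if (min(lam) < -1e-8 * max(lam))
      warning("circulant embedding not non-negative definite; ",
              "truncating spectrum at zero (approximate covariance)")
    lam[neg] <- 0
  }
  m <- 2L * n
  withSeed(seed, {
    w <- complex(length.out = m)
    w[1L] <- rnorm(1)
    w[n + 1L] <- rnorm(1)
    re <- rnorm(n - 1L); im <- rnorm(n - 1L)
    w[2:n] <- (re + 1i * im) / sqrt(2)
    w[m:(n + 2L)] <- Conj(w[2:n])
    x <- Re(fft(sqrt(lam) * w)) / sqrt(m)
    x[seq_len(n)]
  })
}

#' Simulate fractional Brownian motion
#'
#' The cumulative sum of an fGn series with the same Hurst exponent and
#' seed; the path starts at its first increment, with an implicit origin
#' at zero. DFA applied to an fBm path recovers alpha = H + 1.
#'
#' @inheritParams generateFGn
#' @return Numeric vector of length `n`; `diff(c(0, result))` is the
#'   corresponding fGn series.
#' @export
generateFBm <- function(n, hurst, seed = NULL) {
  cumsum(generateFGn(n, hurst, seed))
}

## Latent colored series with DFA alpha ~ target: fGn(H = alpha) for the
## stationary band (alpha <= 1), fBm(H = alpha - 1) for the nonstationary
## band (alpha > 1). This is the alpha = H / H + 1 correspondence the
## noise-band taxonomy relies on.
latentColored <- function(targetAlpha, n, seed) {
  if (targetAlpha > 1) generateFBm(n, targetAlpha - 1, seed)
  else generateFGn(n, targetAlpha, seed)
}

#' Generate a synthetic 6-DOF motion trace with controlled noise color
#'
#' Builds a rigid-body motion trace whose derived speed series has a
#' detrended-fluctuation scaling exponent close to `targetAlpha`. A latent
#' colored series (fGn for `targetAlpha <= 1`, fBm for `targetAlpha > 1`)
#' is shifted to be non-negative and used as the per-frame displacement
#' magnitude; random unit direction vectors distribute that magnitude over
#' the three translation (and, independently, rotation) channels. Because
#' DFA is invariant to an additive offset, the speed series inherits the
#' latent series' scaling exponent exactly at the level of its profile.
#'
#' @param targetAlpha Target DFA exponent of the speed series, in (0, 2).
#' @param nFrames Number of frames (>= 2).
#' @param samplingInterval Seconds per frame (> 0).
#' @param amplitudes Length-2 numeric: typical frame-to-frame speed scale
#'   for translations (mm/s) and rotations (deg/s). Zero amplitudes give
#'   identically zero channels.
#' @param seed Integer seed; channels use independent sub-seeds derived
#'   from it.
#' @param subjectId Identifier stored in the trace.
#' @return A [MotionTrace] object.
#' @examples
#' tr <- generateMotionTrace(1.5, nFrames = 371, samplingInterval = 0.5,
#'                           seed = 7)
#' @export
generateMotionTrace <- function(targetAlpha, nFrames, samplingInterval = 0.5,
                                amplitudes = c(0.1, 0.02), seed = NULL,
                                subjectId = "synthetic") {
  if (!isScalar(targetAlpha) || targetAlpha <= 0 || targetAlpha >= 2)
    invalidParameter("targetAlpha must lie in (0, 2), got %s", format(targetAlpha))
  if (!isCount(nFrames) || nFrames < 2)
    invalidParameter("nFrames must be an integer >= 2, got %s", format(nFrames))
  if (!isScalar(samplingInterval) || samplingInterval <= 0)
    invalidParameter("samplingInterval must be positive, got %s", format(samplingInterval))
  if (length(amplitudes) != 2L || any(!is.finite(amplitudes)) || any(amplitudes < 0))
    invalidParameter("amplitudes must be two non-negative numbers (mm/s, deg/s)")
  if (is.null(seed)) seed <- as.integer(runif(1, 1, 2^31 - 2))
  nFrames <- as.integer(nFrames)
  nSteps <- nFrames - 1L

  channelPath <- function(amp, chanSeed) {
    if (amp == 0) return(matrix(0, nFrames, 3L))
    lat <- latentColored(targetAlpha, nSteps, chanSeed)
    mag <- amp * (lat - min(lat)) * samplingInterval   # displacement per frame
    dirs <- withSeed(subSeed(chanSeed, 1L), {
      m <- matrix(rnorm(3L * nSteps), nSteps, 3L)
      m / sqrt(rowSums(m^2))
    })
    steps <- dirs * mag
    rbind(0, apply(steps, 2L, cumsum))
  }

  MotionTrace(subjectId,
              rotations = channelPath(amplitudes[2L], subSeed(seed, 2L)),
              translations = channelPath(amplitudes[1L], subSeed(seed, 3L)),
              samplingInterval = samplingInterval)
}

#' Describe one group of a synthetic cohort
#'
#' @param label Group label; `"TD"` produces typically-developing records,
#'   `"ASD"`, `"AS"`, `"PDD"`, `"PDDNOS"` produce the corresponding
#'   diagnosis columns.
#' @param nSubjects Number of subjects (>= 1).
#' @param ageMean,ageSD,ageMin,ageMax Truncated-normal age distribution
#'   (years).
#' @param targetAlpha Target DFA exponent of the group's speed series.
#' @param amplitudes Length-2 speed scales (mm/s, deg/s).
#' @param samplingInterval Seconds per frame at the group's site.
#' @param siteId Site identifier written to the phenotype table.
#' @return A list suitable for [CohortSpec()].
#' @export
cohortGroup <- function(label, nSubjects, ageMean = 14, ageSD = 4,
                        ageMin = 6, ageMax = 40, targetAlpha = 1.5,
                        amplitudes = c(0.1, 0.02), samplingInterval = 0.5,
                        siteId = paste0("SITE_", label)) {
  list(label = label, nSubjects = as.integer(nSubjects), ageMean = ageMean,
       ageSD = ageSD, ageMin = ageMin, ageMax = ageMax,
       targetAlpha = targetAlpha, amplitudes = amplitudes,
       samplingInterval = samplingInterval, siteId = siteId)
}

#' Specify a synthetic cohort
#'
#' @param groups List of group descriptions from [cohortGroup()].
#' @param sexRatio Probability that a subject is female, in \[0, 1\].
#' @param medicationRate Probability that a subject is on medication, in
#'   \[0, 1\].
#' @param nFrames Frames per motion trace.
#' @param seed Master seed; subjects receive derived sub-seeds.
#' @return A `CohortSpec` object.
#' @export
CohortSpec <- function(groups, sexRatio = 0.2, medicationRate = 0.15,
                       nFrames = 371L, seed = 1L) {
  if (length(groups) == 0L)
    invalidParameter("CohortSpec requires at least one group")
  new("CohortSpec", groups = groups, sexRatio = sexRatio,
      medicationRate = medicationRate, nFrames = as.integer(nFrames),
      seed = as.integer(seed))
}

## Stratified (quantile) draws from a truncated normal: subject i of n
## sits at quantile (i - 0.5) / n. Ages are therefore deterministic given
## the group size, which guarantees that a larger pool group drawn from
## the same age distribution covers every age bin a smaller reference
## group occupies -- age-matched resampling stays feasible by design.
qtruncnorm <- function(p, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(plo + p * (phi - plo), mean, sd)
}

dsmForLabel <- function(label) {
  switch(label,
         TD = c("TD", "none"),
         ASD = c("ASD", "ASD"),
         AS = c("ASD", "AS"),
         PDD = c("ASD", "PDD"),
         PDDNOS = c("ASD", "PDDNOS"),
         invalidParameter("unknown group label '%s'", label))
}

#' Generate a synthetic multi-site cohort
#'
#' Produces a phenotype table and one motion trace per subject. Each group
#' contributes subjects whose ages are stratified (quantile) draws from
#' its truncated-normal distribution -- deterministic given the group
#' size, so that groups sharing an age distribution always admit
#' age-matched resampling -- and whose traces are built by [generateMotionTrace()] with
#' the group's target scaling exponent, amplitudes and sampling interval.
#' Sex and medication status are Bernoulli draws with the cohort-wide
#' rates; a `medicationRate` of zero yields an all-"no" medication column.
#'
#' @param spec A [CohortSpec()].
#' @return A list with elements `phenotypes` (data.frame with columns
#'   SUB_ID, SITE_ID, DX_PRIMARY, DX_DSM_IV_TR, AGE_AT_SCAN, SEX,
#'   MEDICATION), `traces` (named list of [MotionTrace]), and
#'   `samplingRates` (named vector, seconds per frame by site).
#' @examples
#' spec <- CohortSpec(list(cohortGroup("TD", 5), cohortGroup("ASD", 3)),
#'                    seed = 11)
#' coh <- generateCohort(spec)
#' table(coh$phenotypes$DX_PRIMARY)
#' @export
generateCohort <- function(spec) {
  validObject(spec)
  rows <- list()
  traces <- list()
  rates <- numeric()
  subjIdx <- 0L
  for (gi in seq_along(spec@groups)) {
    g <- spec@groups[[gi]]
    dsm <- dsmForLabel(g$label)
    gseed <- subSeed(spec@seed, gi * 100000L)
    ages <- qtruncnorm((seq_len(g$nSubjects) - 0.5) / g$nSubjects,
                       g$ageMean, g$ageSD, g$ageMin, g$ageMax)
    sexes <- withSeed(subSeed(gseed, 2L),
                      ifelse(runif(g$nSubjects) < spec@sexRatio, "F", "M"))
    meds <- withSeed(subSeed(gseed, 3L),
                     ifelse(runif(g$nSubjects) < spec@medicationRate, "yes", "no"))
    rates[g$siteId] <- g$samplingInterval
    for (si in seq_len(g$nSubjects)) {
      subjIdx <- subjIdx + 1L
      sid <- sprintf("S%05d", subjIdx)
      rows[[subjIdx]] <- data.frame(
        SUB_ID = sid, SITE_ID = g$siteId, DX_PRIMARY = dsm[1L],
        DX_DSM_IV_TR = dsm[2L], AGE_AT_SCAN = round(ages[si], 2),
        SEX = sexes[si], MEDICATION = meds[si],
        stringsAsFactors = FALSE)
      traces[[sid]] <- generateMotionTrace(
        g$targetAlpha, spec@nFrames, g$samplingInterval, g$amplitudes,
        seed = subSeed(gseed, 10L + si), subjectId = sid)
    }
  }
  list(phenotypes = do.call(rbind, rows), traces = traces,
       samplingRates = rates)
}

#' Write a synthetic cohort to disk
#'
#' Motion traces are written in the 6-column whitespace-delimited text
#' format [readMotionFile()] reads (one file per subject, named
#' `<SUB_ID>.1D`), the phenotype table as CSV, and all generation
#' parameters as a JSON sidecar for provenance.
#'
#' @param cohort Result of [generateCohort()].
#' @param dir Output directory (created if needed).
#' @param spec The [CohortSpec()] used, echoed into the sidecar; optional.
#' @return Invisibly, the paths written.
#' @export
writeCohort <- function(cohort, dir, spec = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (sid in names(cohort$traces)) {
    p <- file.path(dir, paste0(sid, ".1D"))
    writeMotionFile(cohort$traces[[sid]], p)
    paths <- c(paths, p)
  }
  phen <- file.path(dir, "phenotypes.csv")
  utils::write.csv(cohort$phenotypes, phen, row.names = FALSE, quote = FALSE)
  side <- file.path(dir, "provenance.json")
  prov <- list(samplingRates = as.list(cohort$samplingRates),
               nSubjects = nrow(cohort$phenotypes))
  if (!is.null(spec))
    prov$spec <- list(nFrames = spec@nFrames, seed = spec@seed,
                      sexRatio = spec@sexRatio,
                      medicationRate = spec@medicationRate,
                      groups = spec@groups)
  jsonlite::write_json(prov, side, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, phen, side))
}
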
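---
title: "Noise signatures of head motion: methods and design choices"
author: "MotionNoise"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Noise signatures of head motion: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MotionNoise)
```

## The problem

Resting-state fMRI pipelines routinely extract six rigid-body motion
parameters per scanner frame (three translations in mm, three rotations in
degrees) and use the implied head speed to censor motion-contaminated
frames. MotionNoise treats that head motion not as a nuisance threshold but
as a signal in its own right: the *noise signature* of a subject's
involuntary head movements. Two properties are estimated per subject and
compared across clinical and demographic groups:

1. the **scaling exponent** alpha of the speed fluctuations, from detrended
   fluctuation analysis (DFA), which places each subject on the taxonomy of
   random processes (white noise at 0.5, pink/1-over-f at 1, brown at 1.5,
   with fractional Gaussian noise (fGn) and fractional Brownian motion
   (fBm) bands in between and beyond), and
2. the **noise-to-signal ratio** of the group's alpha distribution, read
   off a maximum-likelihood Gamma fit: with mean $\mu_\Gamma = ab$ and
   variance $\sigma^2_\Gamma = ab^2$, the Gamma scale is
   $b = \sigma^2_\Gamma / \mu_\Gamma$.

Because multi-site repositories mix scanners with sampling rates below and
above 1 Hz (classes SR0 and SR1) and group sizes are wildly unequal, the
comparison machinery resamples the larger group into age-matched bootstrap
subgroups of exactly the smaller group's size and age-bin composition and
summarizes two-sample Kolmogorov–Smirnov tests across those subgroups.

## Processing chain

For each subject the kinematics stage computes, in order:

1. **Speed.** The Euclidean norm of the per-frame displacement divided by
   the sampling interval, separately for the translation triplet (mm/s)
   and the rotation triplet (deg/s). Angular speed uses the same norm over
   the (roll, pitch, yaw) increments; no quaternion composition is
   attempted because the underlying registration output gives none.
2. **Triangular smoothing.** A symmetric moving average with weights
   $d + 1 - |k|$, $k \in [-d, d]$. At the edges the truncated window is
   renormalized over the available samples, which preserves constants
   everywhere. The default is $d = 1$; see *Smoothing bias* below.
3. **Resampling** to a common 2 Hz by polyphase rational-rate resampling:
   the ratio of target to original rate is approximated by $P/Q$ with
   bounded denominator, the series upsampled by zero-stuffing, filtered
   with a windowed-sinc antialiasing FIR (Kaiser window, $\beta = 5$, ten
   zero crossings per side), decimated, and the filter's group delay
   compensated so the output is aligned with the input. Edges are padded
   by sample replication; a transient of about one filter half-length can
   remain near the boundaries of non-constant signals.
4. **Truncation** to a common 370 points. Subjects too short after
   resampling are excluded and counted, never padded.

## DFA

Given a speed series $x_1,\dots,x_N$, the profile
$X_t = \sum_{i \le t} (x_i - \langle x \rangle)$ is divided into the
leading $\lfloor N/n \rfloor$ non-overlapping windows of length $n$; a
least-squares line is fitted in each window and
$F(n)$ is the RMS residual over all points in complete windows. Alpha is
the least-squares slope of $\log F(n)$ against $\log n$ over every integer
$n \in [4, \lfloor N/10 \rfloor]$. Design choices:

- **All integer window sizes** in the admissible range (34 sizes at
  $N = 370$) rather than log-spaced sizes: the range is fixed by the
  procedure, the spacing is not, and integer enumeration is reproducible
  without a spacing parameter.
- **Leading complete windows only**; the trailing remainder is discarded.
  A reversed second pass would average in the remainder but changes
  nothing asymptotically; the simple tiling matches the plain description
  of the procedure.
- **First-order detrending** (a straight line per window), computed in
  closed form for all windows of a size at once.
- The profile is always the full-length cumulative sum. A windowed
  integration variant (integrating within fixed-length blocks) appears in
  some descriptions of the procedure but contradicts the standard
  definition of the profile; the package implements only the standard
  form, which is also what the reference implementations it is validated
  against compute.

The **growing-window alpha series** re-estimates alpha on every prefix of
the series from 40 points up to $N$, giving each subject a sample of
(at $N = 370$) 331 alpha values whose mean summarizes the subject. Under
the $n \le N/10$ rule a prefix shorter than 50 points admits only the
single window size 4, and a log-log slope needs two; for those prefixes
the largest window size is relaxed minimally to 5 so that every prefix
from 40 points on contributes an estimate. Very short prefixes are noisy
and slightly biased; they are retained because the per-subject mean over
hundreds of prefixes is the quantity carried forward, and trailing
prefixes converge on the full-series alpha (tested).

## The synthetic cohort generator

The generator exists to validate the chain end to end against known
truth, and it defines the study conditions for the package's own
acceptance experiments.

- **Colored noise.** fGn is simulated exactly by circulant embedding
  (Davies–Harte): the closed-form autocovariance
  $\gamma(k) = \tfrac12(|k+1|^{2H} - 2|k|^{2H} + |k-1|^{2H})$ is embedded
  in a circulant matrix diagonalized by FFT and a complex Gaussian vector
  is colored in the frequency domain. For $H \in (0,1)$ the embedding is
  non-negative definite, so the sample paths carry the exact covariance;
  a defensive spectrum truncation (with warning) guards numerically
  negative eigenvalues. fBm is the cumulative sum of fGn. DFA recovers
  $\alpha = H$ for fGn and $H + 1$ for fBm (tested at $N = 2^{14}$ within
  0.05).
- **Motion traces with a target alpha.** A naive construction — colored
  position channels whose increments are normed into speed — does not
  work: the norm (or absolute value) of a Gaussian process has Hermite
  rank 2, so the memory of the increments largely cancels (for fGn with
  Hurst $H$, $|x|$ has exponent $\max(0.5, 2H-1)$), and a target of 1.5
  would produce white speed magnitudes. Instead the generator builds a
  latent colored series with DFA alpha equal to the target (fGn with
  $H = \alpha$ for $\alpha \le 1$, fBm with $H = \alpha - 1$ for
  $\alpha > 1$), shifts it to be non-negative, and uses it directly as the
  per-frame displacement magnitude, distributed over the three channels by
  random unit direction vectors. Since DFA is exactly invariant to
  additive offsets and positive scaling, the speed series recomputed from
  the trace carries the target exponent by construction (recovery at
  $N = 370$: within the estimator's short-series scatter, tested).
- **Phenotypes.** Each group draws ages from a truncated normal via
  stratified quantiles (subject $i$ of $n$ sits at quantile
  $(i - 0.5)/n$). This keeps the marginal distribution while making age
  coverage deterministic: a larger pool drawn from the same distribution
  always covers every age bin a smaller reference occupies, so age-matched
  resampling cannot fail by sampling accident. Sex and medication are
  Bernoulli draws with cohort-wide rates. Default amplitudes (0.1 mm/s,
  0.02 deg/s) put linear speeds in the sub-mm/s to few-mm/s range typical
  of head motion during scanning; they are an order-of-magnitude choice,
  not a calibration to any repository, and every scaling-exponent result
  is exactly invariant to them.
- What the generator does **not** emulate: scanner drift, respiratory and
  cardiac periodicity, burst-like voluntary movements, or any coupling
  between age and motion. Passing tests on synthetic cohorts therefore
  demonstrate that the estimators recover known structure, not that real
  cohorts have that structure.

## Gamma summaries

Shape and scale are fitted by Newton iteration on the shape profile score
$\log a - \psi(a) = \log \bar x - \overline{\log x}$ (tolerance
$10^{-10}$, closed-form small-sample initialization, guarded steps), with
the scale profiled out as $\bar x / a$. The four moments are *derived*
from $(\hat a, \hat b)$, so the identities $\mu = ab$, $\sigma^2 = ab^2$,
skewness $= 2/\sqrt a$, excess kurtosis $= 6/a$ (hence excess kurtosis
$= 1.5 \cdot \text{skewness}^2$) hold exactly for every fit; both raw and
excess kurtosis are reported because conventions differ. Confidence
intervals are asymptotic normal on $(\log a, \log b)$ from the Fisher
information, which keeps intervals positive; coverage at the study's
sample sizes is 93–97% (tested at $n = 456$). The family comparison fits
Normal, Lognormal and Exponential by their closed-form MLEs and ranks all
four families by maximized log-likelihood, breaking exact ties toward
fewer parameters.

## Bootstrap comparison and pooling

`ageMatchedBootstrap()` reproduces the reference group's age-bin
composition exactly in every subgroup (default 2-year bins spanning both
groups; configurable edges), sampling with replacement within bins.
`compareGroups()` fits a Gamma to each subgroup's alpha sample and runs a
two-sample KS test against the reference sample, reporting the p-value
distribution, its mean, its mode (computed on a 20-bin histogram of
log2-transformed p-values, where the distribution is resolvable), and the
count of subgroups with $p \ge 0.05$.

Two pooling modes turn per-subject alpha samples into group samples:

- `subject_mean` (default): one mean alpha per subject. Observations are
  exchangeable across subjects, so KS p-values are calibrated under the
  null — verified by simulation: with identical generating alphas the
  expected overlap fraction is approximately the nominal 95%.
- `pooled`: all growing-window alphas of all subjects concatenated. This
  gives the Gamma fit hundreds of observations per subgroup (useful for
  stable parameter-plane plots) but grossly violates the KS test's
  independence assumption — each subject contributes ~331 strongly
  dependent values — and drives p-values toward zero even under the null.
  It is provided for distributional summaries, not for calibrated testing.

One caveat the package cannot remove: with a single cohort the reference
sample is fixed across all bootstrap iterations, so the 500 p-values are
strongly dependent and the realized overlap fraction of one cohort
scatters widely around its expectation (roughly 0.8–1.0 under the null
at 100-vs-40 subjects). Interpreting the overlap count from a single
comparison should keep that conditioning in mind. No multiple-testing
correction is applied across group comparisons; reports state the raw
per-comparison p-value summaries.

## Smoothing bias

Triangular smoothing attenuates exactly the shortest-window fluctuations
DFA uses, inflating alpha on short series. Measured on 370-point synthetic
series across the fBm band (targets 1.3–1.8): bias +0.21 to +0.09 at
$d = 2$, +0.10 to +0.06 at $d = 1$. The package defaults to $d = 1$, which
keeps the full-chain recovery within ±0.15 across the band while still
damping frame-to-frame jitter; $d$ is configurable in $[0, 6]$ and group
comparisons are unaffected by the shared bias in either case. The bias is
far larger for stationary (fGn-band) inputs, where smoothing whitens the
small-window regime entirely; chain-level alpha recovery should only be
expected in the fBm band the analysis operates in.

## Numerical and degenerate-input choices

- Constant (or linear-in-time-profile) series have $F(n) = 0$ everywhere:
  DFA raises a degenerate-signal error rather than returning an arbitrary
  alpha; the growing-window series skips and counts degenerate prefixes.
- Speeds are clamped at zero after filtering (the FIR can undershoot by a
  rounding margin on non-negative input).
- All randomness flows through explicit seeds; a master seed spawns
  per-group, per-subject and per-channel streams by affine hashing into
  the 32-bit range, and rerunning any stage with the same configuration
  reproduces outputs byte for byte (tested).
- The study-scale problem sizes used throughout the package's own
  validation: series of $N = 4096$ for estimator-theory checks (50
  replicates), $N = 370$ at 2 Hz for chain-level checks, cohorts of
  100 vs 40 subjects with 200–500 bootstrap iterations for the
  comparison experiments.

## Limitations

- Alpha estimates at 370 points carry scatter of roughly ±0.07 (1 SD)
  even for clean synthetic input; single-subject band classifications
  near a band edge are correspondingly uncertain.
- The angular treatment composes Euler-angle increments additively, which
  is accurate for the sub-degree rotations typical of head motion but not
  for large rotations.
- The Gamma family is assumed, not selected per run; `compareFamilies()`
  is provided to check that assumption on any sample.
- Real repository phenotypic files use site-specific numeric codes; this
  package reads a normalized CSV schema (documented in
  `?readPhenotypes`) and leaves the mapping from any particular
  repository's coding to that schema to the user.
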
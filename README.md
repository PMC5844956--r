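# MotionNoise

Noise signatures of involuntary head motion in resting-state fMRI cohorts.

Head motion extracted by volume registration — three translations (mm) and
three rotations (degrees) per scanner frame — is usually treated only as a
censoring criterion. MotionNoise analyzes it as a signal: the scalar speed
of the head is a physiological time series whose fluctuation structure
differs between scanner sampling-rate classes and between clinical
subgroups. The package is aimed at researchers working with multi-site
repositories (heterogeneous sampling rates, strongly unequal group sizes)
who need calibrated group comparisons of motion noise structure.

## What it computes

For each subject, the six motion parameters become uniformly sampled
linear (mm/s) and angular (deg/s) speed profiles (speed → triangular
smoothing → antialiased polyphase resampling to 2 Hz → truncation to 370
points). Each profile is summarized by detrended fluctuation analysis
(DFA): the profile X_t = Σ_{i≤t}(x_i − ⟨x⟩) is detrended in non-overlapping
windows of length n ∈ [4, N/10], the RMS residual F(n) follows
F(n) ∝ n^α, and the scaling exponent α is the log–log slope. α places a
series on the standard noise taxonomy: 0.5 white, 1 pink (1/f), 1.5 brown,
with fractional Gaussian noise (α = H) and fractional Brownian motion
(α = H + 1) bands between and beyond. A growing-window variant yields a
per-subject sample of α values (prefixes of 40 … N points).

Group-level α samples are summarized by maximum-likelihood Gamma fits:
with mean μ = a·b and variance σ² = a·b², the Gamma scale
b = σ²/μ is a noise-to-signal ratio (NSR). Unequal groups are compared by
drawing bootstrap subgroups from the larger group that reproduce the
smaller group's size and age-bin composition exactly, testing each
subgroup against the reference with a two-sample Kolmogorov–Smirnov test,
and reporting the p-value distribution (mean, mode, count with p ≥ 0.05).

A synthetic-cohort generator (exact circulant-embedding fGn/fBm with known
Hurst exponents, embedded into 6-channel motion traces with a target α)
provides ground truth for every stage.

## Worked example

```r
library(MotionNoise)

## colored noise with known truth: fGn (alpha = H), fBm (alpha = H + 1)
x <- generateFGn(4096, hurst = 0.8, seed = 1)
dfaAlpha(x)
#> FluctuationCurve: 406 window sizes in [4, 409], alpha = 0.7417 (R2 = 0.991)
scalingAlpha(dfaAlpha(generateFBm(4096, hurst = 0.8, seed = 1)))
#> [1] 1.838506

## a two-group synthetic cohort: 30 controls (target alpha 1.50),
## 15 ASD (target alpha 1.66), 371 frames at 2 Hz
spec <- CohortSpec(list(
  cohortGroup("TD",  30, targetAlpha = 1.50),
  cohortGroup("ASD", 15, targetAlpha = 1.66)), seed = 42)
coh <- generateCohort(spec)
head(coh$phenotypes, 3)
#>   SUB_ID SITE_ID DX_PRIMARY DX_DSM_IV_TR AGE_AT_SCAN SEX MEDICATION
#> 1 S00001 SITE_TD         TD         none        6.95   M         no
#> 2 S00002 SITE_TD         TD         none        8.14   M         no
#> 3 S00003 SITE_TD         TD         none        8.97   M        yes

## one subject through the kinematics chain and DFA
speed <- speedChain(coh$traces[["S00001"]], "linear")
speed
#> SpeedSeries 'S00001' (linear): 370 points @ 2 Hz, mean 2.433 mm/s
a <- alphaSeries(speed)
a
#> AlphaSample 'S00001': 331 growing-window alphas, mean 1.7004 (0 prefixes skipped)
classifyNoise(meanAlpha(a))
#> [1] "persistent fBm"

## full pipeline: speeds, alphas, age-matched bootstrap comparison
dir <- tempfile(); writeCohort(coh, dir, spec)
cfg <- runConfig(dir, file.path(dir, "phenotypes.csv"), tempfile(),
                 comparisons = list(c("TD", "ASD")),
                 nIterations = 100L, seed = 7)
man <- runPipeline(cfg)
str(man$comparisons$TD_vs_ASD_linear)
#> List of 12
#>  $ pool              : chr "TD"
#>  $ reference         : chr "ASD"
#>  $ kind              : chr "linear"
#>  $ nPool             : int 30
#>  $ nReference        : int 15
#>  $ referenceMeanAlpha: num 1.83
#>  $ subgroupMeanAlpha : num 1.67
#>  $ pMean             : num 0.00269
#>  $ pMode             : num 0.00232
#>  $ nOverlapping      : int 0
#>  $ nIterations       : int 100
#>  $ fracSignificant   : num 1
```

Reading the output: the two groups' mean exponents sit above their 1.50 /
1.66 targets by a shared short-series smoothing bias (documented in the
vignette), both deep in the persistent-fBm band; none of the 100
age-matched bootstrap subgroups of the TD pool overlaps the ASD reference
(all KS p < 0.05), so the groups' α distributions separate cleanly and in
the correct direction. `runPipeline()` also writes `excursions.tsv`
(path lengths and mean speeds), `alphas.tsv`, per-comparison subgroup
tables and a JSON manifest with parameters, seed and exclusions.

On real data, point `runConfig()` at a directory of 6-column motion
parameter files (`<SUB_ID>.1D`) plus a phenotype CSV with header
`SUB_ID, SITE_ID, DX_PRIMARY, DX_DSM_IV_TR, AGE_AT_SCAN, SEX, MEDICATION`
and a site → sampling-interval table (see `?readPhenotypes`).

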
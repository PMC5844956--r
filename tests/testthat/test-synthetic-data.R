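test_that("fGn with H = 0.5 is white: negligible lag-1 autocorrelation", {
  r1 <- sapply(1:20, function(s) {
    x <- generateFGn(4096, 0.5, seed = s)
    cor(x[-1], x[-4096])
  })
  expect_lt(max(abs(r1)), 0.05)
})

test_that("fGn sample autocovariance matches the closed form", {
  lags <- 0:6
  theo <- fgnAutocovariance(0.8, lags)
  emp <- rowMeans(sapply(1:30, function(s) {
    x <- generateFGn(4096, 0.8, seed = s)
    sapply(lags, function(k) mean(x[1:(4096 - k)] * x[(1 + k):4096]))
  }))
  expect_lt(max(abs(emp - theo)), 0.03)
  # closed form itself: gamma(0) = 1, and H = 0.5 gives a delta function
  expect_equal(fgnAutocovariance(0.8, 0), 1)
  expect_equal(fgnAutocovariance(0.5, 1:5), rep(0, 5))
})

test_that("fGn marginals at H = 0.5 are standard normal", {
  fails <- sum(sapply(1:50, function(s) {
    ks.test(generateFGn(1024, 0.5, seed = s), "pnorm")$p.value < 0.01
  }))
  expect_lte(fails, 3)  # binomial(50, 0.01): P(> 3) < 0.002
})

test_that("noise generators are deterministic given a seed and validate input", {
  expect_identical(generateFGn(256, 0.7, seed = 9), generateFGn(256, 0.7, seed = 9))
  expect_identical(generateFBm(256, 0.3, seed = 9), generateFBm(256, 0.3, seed = 9))
  expect_error(generateFGn(100, 1.2, seed = 1), class = "invalidParameterError")
  expect_error(generateFGn(100, 0, seed = 1), class = "invalidParameterError")
  expect_error(generateFGn(1, 0.5, seed = 1), class = "invalidParameterError")
})

test_that("fBm is the cumulative sum of fGn and self-similar", {
  b <- generateFBm(512, 0.8, seed = 4)
  g <- generateFGn(512, 0.8, seed = 4)
  expect_equal(diff(c(0, b)), g)
  # increment variance scales as lag^(2H): log-log slope 1.6 +/- 0.1
  lagvar <- function(x, k) var(x[(1 + k):length(x)] - x[1:(length(x) - k)])
  ks <- 2^(0:6)
  vs <- rowMeans(sapply(1:10, function(s) {
    x <- generateFBm(8192, 0.8, seed = 100 + s)
    sapply(ks, lagvar, x = x)
  }))
  slope <- coef(lm(log(vs) ~ log(ks)))[[2]]
  expect_lt(abs(slope - 1.6), 0.1)
  # H = 0.5: increments uncorrelated (ordinary Brownian motion)
  w <- diff(generateFBm(4096, 0.5, seed = 5))
  expect_lt(abs(cor(w[-1], w[-length(w)])), 0.05)
})

test_that("DFA recovers H from fGn and H + 1 from fBm", {
  for (H in c(0.3, 0.7)) {
    ag <- mean(sapply(1:15, function(s)
      scalingAlpha(dfaAlpha(generateFGn(2^14, H, seed = s)))))
    ab <- mean(sapply(1:15, function(s)
      scalingAlpha(dfaAlpha(generateFBm(2^14, H, seed = 200 + s)))))
    expect_lt(abs(ag - H), 0.05)
    expect_lt(abs(ab - (H + 1)), 0.05)
  }
})

test_that("generateMotionTrace embeds the target exponent in the speed series", {
  # recovery through speed computation alone (no smoothing), 370 points
  rec <- mean(sapply(1:40, function(s) {
    tr <- generateMotionTrace(1.5, 371, 0.5, seed = s)
    scalingAlpha(dfaAlpha(computeSpeed(tr, "linear")))
  }))
  expect_gt(rec, 1.35)
  expect_lt(rec, 1.65)
})

test_that("generateMotionTrace honours amplitudes, seed and validates input", {
  z <- generateMotionTrace(1.5, 100, 0.5, amplitudes = c(0, 0), seed = 1)
  expect_true(all(rotations(z) == 0) && all(translations(z) == 0))
  expect_true(all(speedValues(computeSpeed(z, "linear")) == 0))
  a <- generateMotionTrace(1.2, 100, 0.5, seed = 31)
  b <- generateMotionTrace(1.2, 100, 0.5, seed = 31)
  expect_identical(translations(a), translations(b))
  expect_identical(rotations(a), rotations(b))
  expect_error(generateMotionTrace(2.1, 100, 0.5, seed = 1),
               class = "invalidParameterError")
  expect_error(generateMotionTrace(1.5, 0, 0.5, seed = 1),
               class = "invalidParameterError")
  expect_error(generateMotionTrace(1.5, 100, -1, seed = 1),
               class = "invalidParameterError")
})

test_that("generateCohort produces exact group counts and honest columns", {
  spec <- CohortSpec(list(cohortGroup("TD", 12, targetAlpha = 1.5),
                          cohortGroup("ASD", 5, targetAlpha = 1.66)),
                     medicationRate = 0, nFrames = 60, seed = 3)
  coh <- generateCohort(spec)
  expect_equal(nrow(coh$phenotypes), 17)
  expect_equal(sum(coh$phenotypes$DX_PRIMARY == "TD"), 12)
  expect_equal(sum(coh$phenotypes$DX_PRIMARY == "ASD"), 5)
  expect_true(all(coh$phenotypes$MEDICATION == "no"))
  expect_setequal(names(coh$traces), coh$phenotypes$SUB_ID)
  expect_true(all(coh$phenotypes$AGE_AT_SCAN > 0))
  # determinism
  coh2 <- generateCohort(spec)
  expect_identical(coh$phenotypes, coh2$phenotypes)
  expect_identical(translations(coh$traces[[1]]), translations(coh2$traces[[1]]))
  expect_error(CohortSpec(list()), class = "invalidParameterError")
})
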
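constSpeed <- function(v, n = 100, rate = 2, kind = "linear")
  SpeedSeries("s", kind, rep(v, n), rate)

test_that("computeSpeed is the Euclidean step norm over the sampling interval", {
  # translations advancing (1,0,0) mm per frame at 0.5 s -> 2 mm/s
  tr <- MotionTrace("s", matrix(0, 5, 3), cbind(0:4, 0, 0), 0.5)
  expect_equal(speedValues(computeSpeed(tr, "linear")), rep(2, 4))
  # 3-4-5 triangle at 1 s -> 5 mm/s
  tr <- MotionTrace("s", matrix(0, 3, 3), cbind(c(0, 3, 6), c(0, 4, 8), 0), 1)
  expect_equal(speedValues(computeSpeed(tr, "linear")), c(5, 5))
  # per-frame mode skips the interval division
  tr2 <- MotionTrace("s", matrix(0, 3, 3), cbind(c(0, 3, 6), c(0, 4, 8), 0), 0.5)
  expect_equal(speedValues(computeSpeed(tr2, "linear", perSecond = FALSE)), c(5, 5))
  # zero motion -> zero speed; angular kind reads the rotation triplet
  tr3 <- MotionTrace("s", cbind(c(0, 1, 2), 0, 0), matrix(0, 3, 3), 1)
  expect_equal(speedValues(computeSpeed(tr3, "linear")), c(0, 0))
  expect_equal(speedValues(computeSpeed(tr3, "angular")), c(1, 1))
})

test_that("computeSpeed is invariant to a rigid offset of the channels", {
  tr <- generateMotionTrace(1.3, 80, 0.5, seed = 5)
  shifted <- MotionTrace(subjectId(tr), rotations(tr) + 3,
                         translations(tr) - 7, samplingInterval(tr))
  expect_equal(speedValues(computeSpeed(shifted, "linear")),
               speedValues(computeSpeed(tr, "linear")))
})

test_that("triangularSmooth matches the normalized triangular weights", {
  s <- constSpeed(3)
  expect_equal(speedValues(triangularSmooth(s, 0)), speedValues(s))  # identity
  for (d in 1:4)
    expect_equal(speedValues(triangularSmooth(s, d)), rep(3, 100))   # constants
  # unit impulse, d = 1 -> (1, 2, 1) / 4
  imp <- SpeedSeries("s", "linear", c(0, 0, 1, 0, 0), 2)
  expect_equal(speedValues(triangularSmooth(imp, 1)), c(0, 0.25, 0.5, 0.25, 0))
  expect_error(triangularSmooth(s, -1), class = "invalidParameterError")
  expect_error(triangularSmooth(SpeedSeries("s", "linear", c(1, 2), 2), 1),
               class = "invalidParameterError")
})

test_that("triangularSmooth is a convex combination: bounds never widen", {
  set.seed(42)
  for (d in c(1, 3, 6)) {
    x <- abs(rnorm(200))
    s <- SpeedSeries("s", "linear", x, 2)
    y <- speedValues(triangularSmooth(s, d))
    expect_lte(max(y), max(x) + 1e-12)
    expect_gte(min(y), min(x) - 1e-12)
  }
})

test_that("resampleUniform is the identity at equal rates and preserves constants", {
  s <- constSpeed(2, n = 100, rate = 2)
  expect_equal(speedValues(resampleUniform(s, 2)), speedValues(s))
  up <- resampleUniform(s, 8)
  expect_equal(length(speedValues(up)), 400)
  expect_equal(sampleRate(up), 8)
  expect_lt(max(abs(speedValues(up) - 2)), 0.005)   # passband ripple margin
  down <- resampleUniform(s, 1)
  expect_lt(max(abs(speedValues(down) - 2)), 0.005)
})

test_that("resampleUniform tracks a band-limited signal accurately", {
  # 1 Hz sine sampled at 10 Hz, resampled to 4 Hz: interior RMS error < 1%
  t10 <- seq(0, 20, by = 0.1)
  x <- 2 + sin(2 * pi * t10)       # offset keeps speeds non-negative
  s <- SpeedSeries("s", "linear", x, 10)
  y <- speedValues(resampleUniform(s, 4))
  t4 <- seq(0, by = 0.25, length.out = length(y))
  interior <- 10:(length(y) - 10)
  rmse <- sqrt(mean((y[interior] - (2 + sin(2 * pi * t4[interior])))^2))
  expect_lt(rmse, 0.01)
  expect_error(resampleUniform(SpeedSeries("s", "linear", rep(1, 5), 10), 4),
               class = "insufficientDataError")
})

test_that("truncateSeries keeps exactly the first n points or refuses", {
  s <- SpeedSeries("s", "linear", seq_len(500), 2)
  tr <- truncateSeries(s, 370)
  expect_equal(speedValues(tr), as.numeric(1:370))
  expect_equal(speedValues(truncateSeries(tr, 370)), speedValues(tr))
  short <- SpeedSeries("s", "linear", seq_len(200), 2)
  expect_error(truncateSeries(short, 370), class = "insufficientDataError")
})

test_that("pathExcursion sums speeds into paths and scales linearly", {
  lin <- constSpeed(2, n = 370, rate = 2)
  ang <- constSpeed(0.5, n = 370, rate = 2, kind = "angular")
  ex <- pathExcursion(lin, ang)
  expect_equal(ex$linearPath, 370)        # 2 mm/s * 185 s
  expect_equal(ex$linearMeanSpeed, 2)
  expect_equal(ex$angularPath, 92.5)
  z <- pathExcursion(constSpeed(0, n = 10), constSpeed(0, n = 10, kind = "angular"))
  expect_true(all(unlist(z[-1]) == 0))
  # scaling speeds by c scales paths and means by c
  lin3 <- SpeedSeries("s", "linear", 3 * speedValues(lin), 2)
  ex3 <- pathExcursion(lin3, ang)
  expect_equal(ex3$linearPath, 3 * ex$linearPath)
  expect_equal(ex3$linearMeanSpeed, 3 * ex$linearMeanSpeed)
  expect_error(pathExcursion(constSpeed(1, n = 9), ang),
               class = "invalidParameterError")
})

test_that("the full kinematics chain preserves fBm-band scaling within 0.15", {
  for (target in c(1.4, 1.7)) {
    rec <- mean(sapply(1:12, function(s) {
      tr <- generateMotionTrace(target, 371, 0.5, seed = 5000 + s)
      scalingAlpha(dfaAlpha(speedChain(tr, "linear")))
    }))
    expect_lt(abs(rec - target), 0.15)
  }
})
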
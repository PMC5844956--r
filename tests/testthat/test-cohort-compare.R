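test_that("age-matched bootstrap reproduces the reference bin composition exactly", {
  # reference: 20 subjects aged 10-15, 24 aged 15-20 (total 44)
  refAges <- c(runif(20, 10, 14.9), runif(24, 15, 19.9))
  set.seed(1)
  poolAges <- runif(300, 8, 22)
  ref <- makeAgedRecords(refAges)
  pool <- makeAgedRecords(poolAges)
  pool$SUB_ID <- sprintf("P%03d", seq_len(nrow(pool)))
  plan <- BootstrapPlan(nIterations = 50, ageBinEdges = seq(8, 23, by = 5),
                        seed = 33)
  subs <- ageMatchedBootstrap(pool, ref, plan)
  expect_length(subs, 50)
  edges <- seq(8, 23, by = 5)
  refCounts <- table(cut(ref$AGE_AT_SCAN, edges, right = FALSE, include.lowest = TRUE))
  for (sg in subs) {
    expect_equal(nrow(sg), 44)
    sgCounts <- table(cut(sg$AGE_AT_SCAN, edges, right = FALSE, include.lowest = TRUE))
    expect_equal(as.vector(sgCounts), as.vector(refCounts))
  }
})

test_that("bootstrap is deterministic given the seed and detects infeasible bins", {
  ref <- makeAgedRecords(c(10, 11, 30))
  pool <- makeAgedRecords(c(10.5, 11.5, 12))
  pool$SUB_ID <- sprintf("P%03d", 1:3)
  plan <- BootstrapPlan(nIterations = 5, ageBinEdges = c(8, 12, 28, 32), seed = 2)
  expect_error(ageMatchedBootstrap(pool, ref, plan), "28,32",
               class = "matchingInfeasibleError")
  # pool == reference: plain with-replacement resampling of the reference
  plan2 <- BootstrapPlan(nIterations = 10, seed = 5)
  subs1 <- ageMatchedBootstrap(ref, ref, plan2)
  subs2 <- ageMatchedBootstrap(ref, ref, plan2)
  expect_identical(subs1, subs2)
  expect_true(all(sapply(subs1, nrow) == 3))
  expect_true(all(unlist(lapply(subs1, `[[`, "SUB_ID")) %in% ref$SUB_ID))
})

test_that("ksTwoSample: identical samples give D = 0, disjoint supports D = 1", {
  x <- rnorm(50)
  same <- ksTwoSample(x, x)
  expect_equal(same$D, 0)
  expect_equal(ksTwoSample(1:10, 101:120)$D, 1)
  expect_error(ksTwoSample(numeric(0), x), class = "insufficientDataError")
})

test_that("ksTwoSample is calibrated under the null", {
  rej <- mean(sapply(1:1000, function(s) {
    set.seed(s)
    ksTwoSample(rnorm(500), rnorm(500))$p < 0.05
  }))
  expect_gt(rej, 0.03)
  expect_lt(rej, 0.07)
})

test_that("classifyNoise maps exponents onto the standard bands", {
  expect_equal(classifyNoise(1.66), "persistent fBm")
  expect_equal(classifyNoise(1.73), "persistent fBm")
  expect_equal(classifyNoise(0.8), "persistent fGn")
  expect_equal(classifyNoise(c(0.3, 0.5, 1.0, 1.2, 1.5)),
               c("anti-persistent fGn", "white noise", "pink noise",
                 "anti-persistent fBm", "brown noise"))
  # tolerance controls the landmark half-width
  expect_equal(classifyNoise(1.54, tolerance = 0.05), "brown noise")
  expect_equal(classifyNoise(1.54, tolerance = 0.01), "persistent fBm")
  expect_error(classifyNoise(Inf), class = "domainError")
  expect_error(classifyNoise(-0.1), class = "domainError")
})

test_that("classifyNoise band order is monotone in alpha", {
  bands <- c("anti-persistent fGn", "white noise", "persistent fGn",
             "pink noise", "anti-persistent fBm", "brown noise",
             "persistent fBm")
  labels <- classifyNoise(seq(0.05, 1.95, by = 0.01))
  expect_true(all(diff(match(labels, bands)) >= 0))
})

test_that("compareGroups is deterministic and reproduces a self-comparison", {
  rec <- makeAgedRecords(MotionNoise:::qtruncnorm((1:40 - 0.5) / 40, 14, 4, 6, 40))
  ids <- rec$SUB_ID
  set.seed(77)
  samples <- makeAlphaSamples(ids, rnorm(40, 1.6, 0.07))
  plan <- BootstrapPlan(nIterations = 60, seed = 4)
  r1 <- compareGroups(samples, samples, rec, rec, plan)
  r2 <- compareGroups(samples, samples, rec, rec, plan)
  expect_identical(pValues(r1), pValues(r2))
  expect_identical(r1@subgroupMeanAlphas, r2@subgroupMeanAlphas)
  # subgroup median shape falls inside the reference fit's 95% CI
  medShape <- median(sapply(subgroupFits(r1), gammaShape))
  ci <- gammaCI(referenceFit(r1))$shape
  expect_gt(medShape, ci[1]); expect_lt(medShape, ci[2])
  # report bookkeeping
  expect_equal(length(pValues(r1)), 60)
  expect_true(all(pValues(r1) >= 0 & pValues(r1) <= 1))
  expect_lte(nOverlapping(r1), 60)
})

test_that("compareGroups aborts when too many subgroups fail", {
  rec <- makeAgedRecords(rep(15, 30))
  ids <- rec$SUB_ID
  set.seed(13)
  samples <- makeAlphaSamples(ids, rnorm(30, 1.6, 0.05))
  # drop several pool subjects' alpha samples: most subgroups touch one
  broken <- samples[!names(samples) %in% ids[1:10]]
  plan <- BootstrapPlan(nIterations = 40, seed = 6)
  expect_error(
    compareGroups(broken, samples, rec, rec, plan),
    class = "degenerateDataError")
})

test_that("pooled mode concatenates the full alpha series", {
  ids <- sprintf("S%03d", 1:12)
  samples <- makeAlphaSamples(ids, seq(1.5, 1.7, length.out = 12), nAlphas = 7)
  pooled <- MotionNoise:::poolAlphas(samples, ids, "pooled")
  expect_length(pooled, 12 * 7)
  bysubj <- MotionNoise:::poolAlphas(samples, ids, "subject_mean")
  expect_length(bysubj, 12)
  expect_equal(unname(bysubj), unname(sapply(samples, meanAlpha)))
})
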
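# Independent oracles and small fixture builders shared across tests.
# The DFA oracle below is deliberately naive (explicit loops, lm() fits)
# and shares no code with the package implementation.

naiveDFA <- function(x, nMin = 4, nMax = floor(length(x) / 10)) {
  N <- length(x)
  prof <- cumsum(x - mean(x))
  ns <- nMin:nMax
  Fs <- sapply(ns, function(n) {
    K <- floor(N / n)
    ss <- 0
    for (k in seq_len(K)) {
      seg <- prof[((k - 1) * n + 1):(k * n)]
      tt <- seq_len(n)
      fit <- lm(seg ~ tt)
      ss <- ss + sum(residuals(fit)^2)
    }
    sqrt(ss / (n * K))
  })
  keep <- Fs > 0
  coef(lm(log(Fs[keep]) ~ log(ns[keep])))[[2]]
}

naiveFluctuation <- function(prof, n) {
  N <- length(prof)
  K <- floor(N / n)
  ss <- 0
  for (k in seq_len(K)) {
    seg <- prof[((k - 1) * n + 1):(k * n)]
    tt <- seq_len(n)
    ss <- ss + sum(residuals(lm(seg ~ tt))^2)
  }
  sqrt(ss / (n * K))
}

# Phenotype table with explicit per-subject fields, for selectGroup tests.
makeRecords <- function(dxPrimary, dxDsm, sex = NULL, medication = NULL,
                        age = NULL, site = "SITE_A") {
  n <- length(dxPrimary)
  data.frame(
    SUB_ID = sprintf("T%03d", seq_len(n)),
    SITE_ID = rep_len(site, n),
    DX_PRIMARY = dxPrimary,
    DX_DSM_IV_TR = dxDsm,
    AGE_AT_SCAN = if (is.null(age)) rep(15, n) else age,
    SEX = if (is.null(sex)) rep("M", n) else sex,
    MEDICATION = if (is.null(medication)) rep("no", n) else medication,
    stringsAsFactors = FALSE)
}

# Records with prescribed ages, for bootstrap-composition tests.
makeAgedRecords <- function(ages, prefix = "S") {
  n <- length(ages)
  makeRecords(rep("TD", n), rep("none", n), age = ages)
}

# Synthetic AlphaSample lists keyed by subject id, bypassing DFA, for
# cohort-comparison tests that only exercise the resampling machinery.
makeAlphaSamples <- function(ids, means, nAlphas = 5) {
  out <- lapply(seq_along(ids), function(i) {
    a <- means[i] + seq(-0.01, 0.01, length.out = nAlphas)
    new("AlphaSample", subjectId = ids[i], alphas = a,
        meanAlpha = mean(a), nSkipped = 0L)
  })
  names(out) <- ids
  out
}
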
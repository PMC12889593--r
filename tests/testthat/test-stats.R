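test_that("aggregateTechnical averages microcap replicates per coupon", {
  mk <- function(kps, batch = 1L, coupon = 1L)
    data.frame(microsphere_type = "plain", nanodextran = "Dx-150",
               batch = batch, coupon = coupon,
               microcap = seq_along(kps), kp = kps)
  expect_equal(aggregateTechnical(mk(c(0.6, 0.6, 0.6)))$kp, 0.6)
  expect_equal(aggregateTechnical(mk(c(0.5, 0.6, 0.7)))$kp, 0.6)

  # full study: 11 conditions x 3 batches -> exactly 33 aggregated values
  ds <- simulateStudy(studyPlan(), studyEffectKp(), noiseSd = 0, seed = 1)
  agg <- aggregateTechnical(ds)
  expect_equal(nrow(agg), 33L)
  expect_true(all(agg$n_microcaps == 3L))

  # missing replicate: warn, average what is there
  expect_warning(a <- aggregateTechnical(mk(c(0.4, 0.6))), "fewer than 3")
  expect_equal(a$kp, 0.5)
  expect_equal(a$n_microcaps, 2L)
})

test_that("welchOneTailed reproduces frozen values and the reference implementation", {
  # frozen worked example: t = 2.449, df = 4, p = 0.0352
  w <- welchOneTailed(c(0.5, 0.6, 0.7), c(0.3, 0.4, 0.5), "greater")
  expect_equal(w$t, 2.449490, tolerance = 1e-6)
  expect_equal(w$df, 4.0, tolerance = 1e-9)
  expect_equal(w$p, 0.03524199, tolerance = 1e-6)
  expect_true(w$significant)

  # identical samples: t = 0, one-tailed p = 0.5 by symmetry
  s <- c(1, 2, 3)
  w0 <- welchOneTailed(s, s, "greater")
  expect_equal(w0$t, 0)
  expect_equal(w0$p, 0.5)

  # equal variances and equal n: Welch-Satterthwaite df = n_a + n_b - 2
  a <- c(1, 2, 3, 4); b <- c(11, 12, 13, 14)
  expect_equal(welchOneTailed(a, b, "less")$df, 6)

  # reference oracle: p agrees with stats::t.test to 1e-6 on a fuzzed grid
  set.seed(123)
  for (i in 1:50) {
    na <- sample(3:10, 1); nb <- sample(3:10, 1)
    a <- rnorm(na, runif(1, -2, 2), runif(1, 0.2, 3))
    b <- rnorm(nb, runif(1, -2, 2), runif(1, 0.2, 3))
    dir <- sample(c("greater", "less"), 1)
    mine <- welchOneTailed(a, b, dir)
    ref <- t.test(a, b, alternative = dir)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-6)
    expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-6)
    expect_equal(mine$df, unname(ref$parameter), tolerance = 1e-6)
  }

  expect_error(welchOneTailed(c(1, 1), c(1, 1)), "degenerate test")
  expect_error(welchOneTailed(1, c(1, 2)), "at least 2")
})

test_that("shapiroWilk: exact n = 3 closed form, oracle agreement, calibration", {
  # W = 1 exactly for an evenly spaced triple
  sw <- shapiroWilk(c(1, 2, 3))
  expect_equal(sw$W, 1.0)

  # n = 3 closed form agrees with the base-R reference across fuzzed samples,
  # and W <= 1 always
  set.seed(11)
  for (i in 1:40) {
    x <- rnorm(3, sd = runif(1, 0.1, 10))
    mine <- shapiroWilk(x)
    ref <- shapiro.test(x)
    expect_equal(mine$W, unname(ref$statistic), tolerance = 1e-6)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-4)
    expect_lte(mine$W, 1)
  }

  # Monte-Carlo calibration at n = 3: rejection rate at alpha = 0.05 within
  # the binomial 95% CI over 2000 normal samples
  set.seed(2024)
  rej <- mean(vapply(1:2000, function(i) shapiroWilk(rnorm(3))$p < 0.05,
                     logical(1)))
  ci <- 0.05 + c(-1, 1) * 1.96 * sqrt(0.05 * 0.95 / 2000)
  expect_gte(rej, ci[1])
  expect_lte(rej, ci[2])

  expect_error(shapiroWilk(rep(2, 5)), "degenerate sample")
  expect_error(shapiroWilk(c(1, 2)), "\\[3, 50\\]")
})

test_that("confidenceInterval95 matches the t-quantile oracle", {
  expect_equal(unname(confidenceInterval95(rep(0.4, 4))), c(0.4, 0.4))
  ci <- confidenceInterval95(c(0.5, 0.6, 0.7))
  half <- 4.302653 * 0.1 / sqrt(3)     # t_{0.975, 2} from reference tables
  expect_equal(unname(ci), c(0.6 - half, 0.6 + half), tolerance = 1e-5)
  expect_true(ci[["low"]] <= 0.6 && 0.6 <= ci[["high"]])
  expect_error(confidenceInterval95(1), "at least 2")
})

test_that("the hypothesis battery enumerates the six primary comparisons", {
  specs <- hypothesisSpecs()
  expect_equal(nrow(specs), 6L)
  expect_equal(sum(specs$effect == "size_exclusion"), 1L)
  expect_equal(sum(specs$effect == "volume_exclusion"), 1L)
  expect_equal(sum(specs$effect == "attachment"), 4L)
  expect_true(all(specs$direction == "greater"))

  ds <- simulateStudy(studyPlan(), studyEffectKp(), seed = 1)
  res <- suppressWarnings(runHypothesisBattery(ds))
  expect_equal(nrow(res), 6L)
  expect_equal(attr(res, "n_comparisons"), 6L)

  # missing condition: named error
  dsx <- ds[ds$nanodextran != "Dx-2000", ]
  expect_error(suppressWarnings(runHypothesisBattery(dsx)),
               "plain/Dx-2000")
})

test_that("a constructed 30% size-exclusion effect is detected with high power", {
  tk <- studyEffectKp()
  tk[] <- 0.7
  tk["plain/Dx-150"] <- 0.7
  tk["plain/Dx-2000"] <- 0.7 * 0.7          # a true 30% decrease
  hits <- vapply(1:50, function(s) {
    ds <- simulateStudy(studyPlan(), tk, noiseSd = 0.05, seed = s)
    res <- suppressWarnings(runHypothesisBattery(ds))
    res$significant[res$effect == "size_exclusion"]
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("null rejection rates match the Welch test's true size at n = 3", {
  # Independent oracle: the exact size of the one-tailed Welch test at
  # alpha = 0.05 with n = 3 vs 3 normal samples is 0.0396 (measured with
  # 200k replicates of stats::t.test on N(0,1) draws; Welch-Satterthwaite's
  # random df makes the test conservative at this n). Each battery test's
  # null rejection rate over 300 simulated datasets must lie within the
  # binomial 95% CI of that size.
  trueSize <- 0.0396
  nrep <- 300L
  tk <- studyEffectKp()
  tk[] <- 0.7                                   # all conditions identical
  rej <- matrix(FALSE, nrep, 6L)
  for (i in seq_len(nrep)) {
    ds <- simulateStudy(studyPlan(), tk, noiseSd = 0.05, seed = 5000L + i)
    rej[i, ] <- suppressWarnings(runHypothesisBattery(ds))$significant
  }
  ci <- trueSize + c(-1, 1) * 1.96 * sqrt(trueSize * (1 - trueSize) / nrep)
  rates <- colMeans(rej)
  expect_true(all(rates >= ci[1] & rates <= ci[2]))
})

test_that("strict normality gating aborts on a non-normal sample", {
  ds <- simulateStudy(studyPlan(), studyEffectKp(), noiseSd = 0.05, seed = 1)
  # inject a wildly skewed condition at the coupon level
  ds$kp[ds$microsphere_type == "plain" & ds$nanodextran == "Dx-150"] <-
    rep(c(0.1, 0.1001, 5), each = 3)
  expect_warning(runHypothesisBattery(ds), "normality gate")
  expect_error(runHypothesisBattery(ds, normality = "strict"),
               "normality gate")
})
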
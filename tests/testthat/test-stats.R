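test_that("derived metrics reproduce worked ratio arithmetic", {
  t <- deriveMetrics(data.frame(bw_kg = 40, gm_mL = 50, wm_mL = 25,
                                csf_mL = 10))
  expect_equal(t$gm_wm_ratio, 2.0)
  expect_equal(t$total_mL, 75)
  # template-volume worked example
  t2 <- deriveMetrics(data.frame(bw_kg = 47.9, gm_mL = 50.3, wm_mL = 42.8,
                                 csf_mL = 33.9))
  expect_equal(t2$total_mL, 50.3 + 42.8, tolerance = 1e-12)
  expect_equal(round(t2$csf_total_ratio, 1), 0.4)
  expect_equal(round(t2$total_perkg, 1), 1.9)
  # identical subjects -> zero spread in every metric
  rep3 <- deriveMetrics(data.frame(bw_kg = rep(50, 4), gm_mL = rep(51, 4),
                                   wm_mL = rep(35, 4), csf_mL = rep(30, 4)))
  for (cc in c("gm_wm_ratio", "gm_total_ratio", "csf_total_ratio",
               "total_perkg"))
    expect_identical(sd(rep3[[cc]]), 0)
  expect_error(deriveMetrics(data.frame(bw_kg = 50, gm_mL = 10, wm_mL = 0,
                                        csf_mL = 1)), "WM")
})

test_that("a noise-free generating model is fit exactly", {
  set.seed(8)
  n <- 24
  t <- data.frame(sex = rep(c("male", "female"), each = n / 2),
                  age_months = runif(n, 8, 20), bw_kg = runif(n, 40, 70))
  t$gm_mL <- 0.2 * t$bw_kg + 5
  f <- suppressWarnings(fitVolumeModel(t, "gm_mL"))  # lm warns on an exact fit
  co <- f$coefficients
  expect_equal(co$estimate[co$term == "bw"], 0.2, tolerance = 1e-10)
  expect_equal(co$partial_explained_variance_pct[co$term == "bw"], 100,
               tolerance = 1e-6)
  expect_error(fitVolumeModel(t[t$sex == "male", ], "gm_mL"), "sexes")
})

test_that("partial explained variance equals the residual-correlation oracle", {
  co <- makeCohort(cohortSpec(seed = 12L))
  f <- fitVolumeModel(co, "gm_mL")
  # independent route: squared correlation of the residuals of y and bw
  # after regressing each on the other covariates
  sex <- as.numeric(co$sex == "female")
  ry <- residuals(lm(co$gm_mL ~ co$age_months + sex))
  rx <- residuals(lm(co$bw_kg ~ co$age_months + sex))
  oracle <- 100 * cor(ry, rx)^2
  got <- f$coefficients$partial_explained_variance_pct[
    f$coefficients$term == "bw"]
  expect_equal(got, oracle, tolerance = 1e-8)
})

test_that("null covariates show the finite-sample baseline partial variance", {
  # with no true effect the squared partial correlation has mean
  # 1 / (df + 1), here df = 34 (exact Beta(1/2, df/2) expectation)
  pv <- vapply(1:400, function(i) {
    f <- fitVolumeModel(makeCohort(cohortSpec(partialVarBwGm = 0,
                                              seed = 50000L + i)), "gm_mL")
    f$coefficients$partial_explained_variance_pct[f$coefficients$term == "bw"]
  }, numeric(1))
  expect_equal(mean(pv), 100 / 35, tolerance = 0.2 * 100 / 35)
})

test_that("volume adjustment removes covariate effects and keeps the mean", {
  co <- makeCohort(cohortSpec(seed = 14L))
  f <- fitVolumeModel(co, "gm_mL")
  adj <- adjustVolumes(co, f)
  expect_equal(mean(adj$gm_mL_adj), mean(co$gm_mL), tolerance = 1e-10)
  # adjusted values no longer depend on body weight
  f2 <- fitVolumeModel(transform(adj, gm_mL = gm_mL_adj), "gm_mL")
  expect_lt(abs(f2$coefficients$estimate[f2$coefficients$term == "bw"]), 1e-9)
  # zero coefficients leave the data untouched
  f0 <- f
  f0$coefficients$estimate[] <- 0
  adj0 <- adjustVolumes(co, f0)
  expect_identical(adj0$gm_mL_adj, co$gm_mL)
})

test_that("group comparison and normality checks behave as calibrated tests", {
  co <- makeCohort(cohortSpec(seed = 16L))
  # groups with identical distributions -> p = 1
  same <- co
  same$gm_mL[same$sex == "male"] <- rep(c(50, 52), 13)
  same$gm_mL[same$sex == "female"] <- rep(c(50, 52), 6)
  gc0 <- groupCompare(same, "gm_mL")
  expect_gt(gc0$p_value, 0.99)
  nc <- normalityCheck(co, "gm_mL")
  expect_true(nc$ks_p > 0 && nc$shapiro_p > 0)
  expect_error(groupCompare(co[co$sex == "male", ], "gm_mL"), "two groups")
})

test_that("the sex comparison has power and Shapiro-Wilk is calibrated", {
  set.seed(31)
  rejections <- 0L
  shapiro_rej <- 0L
  nsim <- 1000L
  for (i in seq_len(nsim)) {
    a <- rnorm(26, 1.0, 0.1)
    b <- rnorm(12, 0.8, 0.1)
    if (t.test(a, b)$p.value < 0.05) rejections <- rejections + 1L
    if (shapiro.test(rnorm(38))$p.value < 0.05) shapiro_rej <- shapiro_rej + 1L
  }
  expect_gt(rejections / nsim, 0.95)
  expect_gt(shapiro_rej / nsim, 0.03)
  expect_lt(shapiro_rej / nsim, 0.07)
})
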
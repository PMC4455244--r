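test_that("noiseless segmentation with exact priors reproduces the truth", {
  bp <- cleanBase()
  priors <- smoothPriors(bp$truth@labels)
  seg <- segmentVolume(bp$volume, priors)
  hl <- hardLabels(seg)
  expect_gte(mean(hl@data == bp$truth@labels@data), 0.999)
  # T1w ordering of the fitted class means
  expect_true(seg@mu[["csf"]] < seg@mu[["gm"]])
  expect_true(seg@mu[["gm"]] < seg@mu[["wm"]])
})

test_that("segmentation at 10 percent-gap noise keeps Dice above 0.90", {
  bp <- cleanBase()
  nv <- noisyVolume(bp, 2)   # GM-WM gap is 20 intensity units
  seg <- segmentVolume(nv, smoothPriors(bp$truth@labels))
  hl <- hardLabels(seg)
  expect_gte(diceCoef(hl@data == 2L, bp$truth@labels@data == 2L), 0.90)
  expect_gte(diceCoef(hl@data == 3L, bp$truth@labels@data == 3L), 0.90)
})

test_that("posteriors normalise exactly and the log-likelihood is monotone", {
  bp <- cleanBase()
  nv <- noisyVolume(bp, 5)
  seg <- segmentVolume(nv, smoothPriors(bp$truth@labels))
  s <- seg@posteriors$gm@data + seg@posteriors$wm@data +
    seg@posteriors$csf@data + seg@posteriors$bg@data
  expect_lt(max(abs(s - 1)), 1e-6)
  expect_true(all(diff(seg@logLik) >= -1e-6 * abs(seg@logLik[1])))
  expect_true(seg@converged)
})

test_that("uniform priors reduce to an unsupervised mixture fit", {
  bp <- cleanBase()
  nv <- noisyVolume(bp, 2)
  d <- volDim(nv)
  unif <- lapply(1:3, function(i)
    BrainVolume(array(0.25, d), affine = nv@affine))
  names(unif) <- c("gm", "wm", "csf")
  seg <- segmentVolume(nv, unif)
  mu <- sort(seg@mu)
  truth <- c(0, 25, 55, 75)
  # non-zero means within 5 percent, background within 1 intensity unit
  expect_lt(abs(mu[1] - 0), 1)
  expect_lt(max(abs(mu[2:4] - truth[2:4]) / truth[2:4]), 0.05)
})

test_that("tissue volumes count posteriors and conserve the grid", {
  # 1000 all-GM voxels at 1 mm^3 -> 1 mL
  d <- c(10, 10, 10)
  mk <- function(vals) BrainVolume(array(vals, d))
  seg <- new("SegmentationResult",
             posteriors = list(csf = mk(0), gm = mk(1), wm = mk(0), bg = mk(0)),
             mu = c(csf = 1, gm = 2, wm = 3, bg = 0),
             sigma2 = rep(1, 4), logLik = 0, converged = TRUE,
             iterations = 1L)
  tv <- tissueVolumes(seg)
  expect_equal(tv$gm_mL, 1.0)
  expect_identical(tv$total_brain_mL, tv$gm_mL + tv$wm_mL)
  # phantom volumes from soft posteriors within 5 percent at default noise
  bp <- cleanBase()
  nv <- noisyVolume(bp, 5)
  seg2 <- segmentVolume(nv, smoothPriors(bp$truth@labels))
  tv2 <- tissueVolumes(seg2)
  truth <- bp$truth@trueVolumes
  expect_lt(abs(tv2$gm_mL - truth[["gm"]]) / truth[["gm"]], 0.05)
  expect_lt(abs(tv2$wm_mL - truth[["wm"]]) / truth[["wm"]], 0.05)
  expect_lt(abs(tv2$csf_mL - truth[["csf"]]) / truth[["csf"]], 0.05)
  # conservation: all four classes sum to the grid volume
  tot <- tv2$gm_mL + tv2$wm_mL + tv2$csf_mL +
    sum(seg2@posteriors$bg@data) * voxelVolume(nv) / 1000
  expect_equal(tot, prod(volDim(nv)) * voxelVolume(nv) / 1000,
               tolerance = 1e-9)
  # hard volumes also land near the truth
  tvh <- tissueVolumes(seg2, hard = TRUE)
  expect_lt(abs(tvh$gm_mL - truth[["gm"]]) / truth[["gm"]], 0.05)
})

test_that("homogeneity check flags but never excludes outliers", {
  bp <- cleanBase()
  subs <- lapply(1:8, function(i) noisyVolume(bp, 3, seed = 200L + i))
  names(subs) <- sprintf("s%d", 1:8)
  rep0 <- homogeneityCheck(subs)
  expect_false(any(rep0$flagged))
  expect_true(all(rep0$mean_correlation > 0.9))
  # identical subjects: correlations exactly 1
  same <- rep(list(bp$volume), 3)
  rep1 <- homogeneityCheck(same)
  expect_true(all(abs(rep1$mean_correlation - 1) < 1e-12))
  # one pure-noise subject is flagged yet still reported
  set.seed(5)
  subs$s8@data <- array(rnorm(length(subs$s8@data)), volDim(subs$s8))
  rep2 <- homogeneityCheck(subs)
  expect_true(rep2$flagged[rep2$subject == "s8"])
  expect_identical(nrow(rep2), 8L)
  expect_error(homogeneityCheck(subs[1:2]), "at least 3")
})
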
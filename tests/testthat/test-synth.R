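test_that("base phantom has exact class intensities, determinism and conservation", {
  sp <- phantomSpec(noiseSd = 0, biasAmplitude = 0)
  bp <- cleanBase()
  lab <- bp$truth@labels@data
  expect_true(all(bp$volume@data[lab == 3L] == 75))
  expect_true(all(bp$volume@data[lab == 0L] == 0))
  # conservation: class counts partition the grid exactly
  counts <- table(factor(lab, levels = 0:3))
  expect_identical(as.numeric(sum(counts)), prod(volDim(bp$volume)))
  expect_equal(unname(bp$truth@trueVolumes),
               unname(c(counts["1"], counts["2"], counts["3"]) *
                        voxelVolume(bp$volume) / 1000))
  # same spec twice -> bit-identical
  bp2 <- makeBasePhantom(sp)
  expect_identical(bp$volume@data, bp2$volume@data)
  expect_identical(bp$truth@labels@data, bp2$truth@labels@data)
})

test_that("spherical WM volume matches the analytic sphere", {
  r <- 8
  sp <- phantomSpec(brainAxes = c(12, 12, 12), wmRadius = r / 12,
                    gyralAmplitude = 0, ventricles = FALSE,
                    noiseSd = 0, biasAmplitude = 0)
  bs <- makeBasePhantom(sp)
  analytic <- 4 / 3 * pi * r^3 / 1000
  expect_lt(abs(bs$truth@trueVolumes[["wm"]] - analytic) / analytic, 0.02)
})

test_that("GM shell separates the WM core from exterior CSF", {
  bp <- cleanBase()
  lab <- bp$truth@labels@data
  d <- dim(lab)
  # flood the exterior (background + connected CSF) from the grid boundary
  ext <- lab == 0L
  reach <- array(FALSE, d)
  reach[1, , ] <- TRUE; reach[d[1], , ] <- TRUE
  reach[, 1, ] <- TRUE; reach[, d[2], ] <- TRUE
  reach[, , 1] <- TRUE; reach[, , d[3]] <- TRUE
  reach <- reach & (ext | lab == 1L)
  repeat {
    grown <- reach
    grown[-1, , ] <- grown[-1, , ] | reach[-d[1], , ]
    grown[-d[1], , ] <- grown[-d[1], , ] | reach[-1, , ]
    grown[, -1, ] <- grown[, -1, ] | reach[, -d[2], ]
    grown[, -d[2], ] <- grown[, -d[2], ] | reach[, -1, ]
    grown[, , -1] <- grown[, , -1] | reach[, , -d[3]]
    grown[, , -d[3]] <- grown[, , -d[3]] | reach[, , -1]
    grown <- grown & (ext | lab == 1L)
    if (identical(grown, reach)) break
    reach <- grown
  }
  extCsf <- reach & lab == 1L
  # no WM voxel may touch exterior CSF face-on
  wm <- lab == 3L
  touch <- FALSE
  for (ax in 1:3) {
    n <- d[ax]
    lo <- slice.index(wm, ax) < n
    hi <- slice.index(wm, ax) > 1
    shifted <- array(FALSE, d)
    if (ax == 1) { shifted[-n, , ] <- extCsf[-1, , ]; shifted[n, , ] <- FALSE }
    if (ax == 2) { shifted[, -n, ] <- extCsf[, -1, ]; shifted[, n, ] <- FALSE }
    if (ax == 3) { shifted[, , -n] <- extCsf[, , -1]; shifted[, , n] <- FALSE }
    touch <- touch || any(wm & shifted)
    if (ax == 1) { shifted[-1, , ] <- extCsf[-n, , ]; shifted[1, , ] <- FALSE }
    if (ax == 2) { shifted[, -1, ] <- extCsf[, -n, ]; shifted[, 1, ] <- FALSE }
    if (ax == 3) { shifted[, , -1] <- extCsf[, , -n]; shifted[, , 1] <- FALSE }
    touch <- touch || any(wm & shifted)
  }
  expect_false(touch)
  # AC and PC lie inside the GM+WM envelope
  ac <- worldToIndex(bp$volume, matrix(bp$truth@landmarks@coords["AC", ], 1))
  pc <- worldToIndex(bp$volume, matrix(bp$truth@landmarks@coords["PC", ], 1))
  expect_true(lab[matrix(round(ac) + 1, 1)] %in% 2:3)
  expect_true(lab[matrix(round(pc) + 1, 1)] %in% 2:3)
})

test_that("artefact-free subject with identity similarity equals the base", {
  bp <- cleanBase()
  sp0 <- phantomSpec(noiseSd = 0, biasAmplitude = 0, deformAmplitude = 0)
  sub <- makeSubject(bp, sp0, 5L, similarity = diag(4))
  expect_equal(sub$volume@data, bp$volume@data)
  expect_identical(sub$truth@labels@data, bp$truth@labels@data)
  # with noise only, the residual is exactly the additive noise
  spn <- phantomSpec(noiseSd = 3, biasAmplitude = 0, deformAmplitude = 0)
  subn <- makeSubject(bp, spn, 5L, similarity = diag(4))
  resid <- subn$volume@data - bp$volume@data
  expect_equal(sd(as.numeric(resid)), 3, tolerance = 0.02)
})

test_that("subject generation is deterministic and rejects folding fields", {
  bp <- cleanBase()
  sp <- phantomSpec(noiseSd = 2, biasAmplitude = 0.1)
  a <- makeSubject(bp, sp, 21L)
  b <- makeSubject(bp, sp, 21L)
  expect_identical(a$volume@data, b$volume@data)
  expect_identical(a$truth@labels@data, b$truth@labels@data)
  jac <- fieldJacobian(a$truth@trueTransform@field)
  expect_gt(min(jac), 0)
})

test_that("warped label volumes are Jacobian-consistent", {
  bp <- cleanBase()
  # pure smooth deformation: volume change bounded by the Jacobian range
  sp <- phantomSpec(noiseSd = 0, biasAmplitude = 0, deformAmplitude = 2)
  sub <- makeSubject(bp, sp, 31L, similarity = diag(4))
  jac <- fieldJacobian(sub$truth@trueTransform@field)
  brain <- bp$truth@labels@data > 0
  jr <- range(jac[brain])
  vb <- sum(bp$truth@trueVolumes[c("gm", "wm")])
  vs <- sum(sub$truth@trueVolumes[c("gm", "wm")])
  # t maps subject -> base, so subject volume scales like 1 / J
  expect_gt(vs / vb, 1 / jr[2] - 0.03)
  expect_lt(vs / vb, 1 / jr[1] + 0.03)
  # pure isotropic scaling: volume scales exactly like s^-3 (up to voxels)
  s <- 1.08
  sub2 <- makeSubject(bp, phantomSpec(noiseSd = 0, biasAmplitude = 0,
                                      deformAmplitude = 0), 32L,
                      similarity = diag(c(s, s, s, 1)))
  expect_equal(sum(sub2$truth@trueVolumes) / sum(bp$truth@trueVolumes),
               s^-3, tolerance = 0.03)
})

test_that("cohort generation honours the demographic spec and null effects", {
  cs <- cohortSpec(seed = 3L)
  co <- makeCohort(cs)
  expect_identical(nrow(co), 38L)
  expect_identical(sum(co$sex == "male"), 26L)
  expect_identical(sum(co$sex == "female"), 12L)
  expect_true(all(co$bw_kg > 0) && all(co$age_months > 0))
  expect_identical(makeCohort(cs), co)
  # zero partial variance: the fitted body-weight effect is centred on zero
  coefs <- vapply(1:400, function(i) {
    f <- fitVolumeModel(makeCohort(cohortSpec(partialVarBwGm = 0,
                                              seed = 40000L + i)), "gm_mL")
    f$coefficients$estimate[f$coefficients$term == "bw"]
  }, numeric(1))
  expect_lt(abs(mean(coefs)), 0.02)
})

test_that("infeasible cohort calibration errors", {
  expect_error(cohortSpec(partialVarBwGm = 1), "partial variances")
  expect_error(makeCohort(cohortSpec(effectBwOnGm = 0)), "zero effect")
})
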
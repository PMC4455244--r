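test_that("linear registration of a volume to itself stays at identity", {
  bp <- cleanBase()
  r <- registerLinear(bp$volume, bp$volume, dof = 6L)
  expect_lt(rotationAngleDeg(r$transform), 0.1)
  expect_lt(sqrt(sum(r$transform[1:3, 4]^2)), 0.1)
  expect_gte(r$similarity, r$initial_similarity)
})

test_that("linear registration recovers a known rigid transform", {
  bp <- cleanBase()
  ang <- 5 * pi / 180
  A <- diag(4)
  A[1:3, 1:3] <- rbind(c(cos(ang), -sin(ang), 0),
                       c(sin(ang), cos(ang), 0), c(0, 0, 1))
  A[1:3, 4] <- c(3, -2, 1)
  sub <- makeSubject(bp, phantomSpec(noiseSd = 0, biasAmplitude = 0,
                                     deformAmplitude = 0), 7L, similarity = A)
  r <- registerLinear(sub$volume, bp$volume, dof = 6L)
  # the registration recovers the inverse of the generating map
  err <- r$transform %*% A
  expect_lt(rotationAngleDeg(err), 0.5)
  expect_lt(sqrt(sum(err[1:3, 4]^2)), 0.2)
})

test_that("affine registration recovers a known isotropic scale", {
  bp <- cleanBase()
  s <- 1.05
  sub <- makeSubject(bp, phantomSpec(noiseSd = 0, biasAmplitude = 0,
                                     deformAmplitude = 0), 8L,
                     similarity = diag(c(s, s, s, 1)))
  r <- registerLinear(sub$volume, bp$volume, dof = 12L)
  recovered <- det(solve(r$transform)[1:3, 1:3])^(1 / 3)
  expect_equal(recovered, s, tolerance = 0.01)
})

test_that("the NCC objective is invariant to affine intensity rescaling", {
  bp <- cleanBase()
  v2 <- bp$volume
  v2@data <- 3 * v2@data + 10
  r1 <- registerLinear(bp$volume, bp$volume, dof = 6L, levels = 2L,
                       maxit = 50L)
  r2 <- registerLinear(v2, bp$volume, dof = 6L, levels = 2L, maxit = 50L)
  expect_equal(r1$initial_similarity, r2$initial_similarity, tolerance = 1e-9)
})

test_that("demons registration of identical volumes yields a near-zero field", {
  bp <- cleanBase()
  nl <- registerNonlinear(bp$volume, bp$volume)
  rms <- sqrt(mean(nl$field@field^2))
  expect_lt(rms, 0.1)
  expect_identical(nl$fold_fraction, 0)
})

test_that("demons recovers a known smooth deformation", {
  bp <- cleanBase()
  sp <- phantomSpec(noiseSd = 0, biasAmplitude = 0, deformAmplitude = 3)
  sub <- makeSubject(bp, sp, 11L, similarity = diag(4))
  nl <- registerNonlinear(sub$volume, bp$volume)
  # SSD within every schedule stage is non-increasing
  for (st in nl$ssd_trace) expect_lte(st$ssd_after, st$ssd_before)
  # full-resolution SSD reduced by at least 70 percent
  x <- ovatlas:::worldGrid(bp$volume)
  u <- ovatlas:::sampleField(nl$field, x)
  idx <- worldToIndex(sub$volume, x + u)
  w <- array(ovatlas:::cpp_sample(as.numeric(sub$volume@data),
                                  as.integer(volDim(sub$volume)), idx, 1L),
             volDim(bp$volume))
  s0 <- mean((sub$volume@data - bp$volume@data)^2)
  s1 <- mean((w - bp$volume@data)^2)
  expect_lt(s1, 0.3 * s0)
  # the recovered field approximates the inverse of the generating map to
  # sub-voxel accuracy inside the brain (flat-interior components of the
  # truth are unobservable; see the methods vignette)
  inv <- invertTransform(sub$truth@trueTransform, grid = bp$volume)
  brain <- array(bp$truth@labels@data > 0, dim(inv@field@field))
  err <- sqrt(mean(((nl$field@field - inv@field@field)^2)[brain]))
  expect_lt(err, 0.5)
})

test_that("transform algebra: composition, inversion and means", {
  ang <- 6 * pi / 180
  T1 <- diag(4)
  T1[1:2, 1:2] <- rbind(c(cos(ang), -sin(ang)), c(sin(ang), cos(ang)))
  T1[1:3, 4] <- c(2, -1, 3)
  # compose with exact inverse
  comp <- composeTransforms(TransformChain(T1), invertAffine(TransformChain(T1)))
  expect_lt(max(abs(comp@affine - diag(4))), 1e-9)
  # log-mean of T and its inverse is the identity
  mt <- meanTransform(list(T1, solve(T1)))
  expect_lt(max(abs(mt@affine - diag(4))), 1e-9)
  # mean of N identical transforms is that transform
  mt2 <- meanTransform(list(T1, T1, T1))
  expect_lt(max(abs(mt2@affine - T1)), 1e-9)
  expect_error(invertAffine(matrix(0, 4, 4)))
})

test_that("chains with fields invert and compose to identity numerically", {
  bp <- cleanBase()
  sp <- phantomSpec(noiseSd = 0, biasAmplitude = 0, deformAmplitude = 2)
  sub <- makeSubject(bp, sp, 13L)
  ch <- sub$truth@trueTransform
  inv <- invertTransform(ch, grid = bp$volume)
  comp <- composeTransforms(ch, inv)
  expect_lt(max(abs(comp@affine %*% solve(comp@affine) - diag(4))), 1e-9)
  # interior residual displacement of t o t^-1 is far below a voxel
  d <- volDim(bp$volume)
  core <- array(FALSE, d)
  core[9:(d[1] - 8), 9:(d[2] - 8), 9:(d[3] - 8)] <- TRUE
  x <- ovatlas:::worldGrid(bp$volume)[as.logical(core), , drop = FALSE]
  resid <- applyTransform(comp, x) - x
  expect_lt(sqrt(mean(resid^2)), 0.05)
})

test_that("left-right flip is an exact involution and mirrors landmarks", {
  bp <- cleanBase()
  f <- flipLR(bp$volume)
  expect_identical(flipLR(f)@data, bp$volume@data)
  # landmark mirroring: eye_L maps onto eye_R with x negated
  co <- bp$truth@landmarks@coords
  refl <- co %*% diag(c(-1, 1, 1))
  expect_equal(unname(refl["eye_L", ]), unname(co["eye_R", ]))
  # an x-symmetric volume is invariant under the flip
  sym <- bp$volume
  sym@data <- (sym@data + flipLR(sym)@data) / 2
  expect_equal(flipLR(sym)@data, sym@data)
})
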
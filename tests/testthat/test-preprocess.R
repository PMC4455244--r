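test_that("bias field estimation is near unity on bias-free input", {
  bp <- cleanBase()
  v <- noisyVolume(bp, 2)
  mask <- bp$truth@labels@data > 0
  v@data[v@data <= 0] <- 0.1
  cb <- correctBias(v, mask)
  expect_lt(max(abs(cb$bias_field@data[mask] - 1)), 0.02)
  # normalisation contract: mean field over the mask is 1
  expect_equal(mean(cb$bias_field@data[mask]), 1, tolerance = 1e-6)
})

test_that("a known linear ramp bias is removed", {
  bp <- cleanBase()
  d <- volDim(bp$volume)
  xhat <- array(rep(seq(-0.5, 0.5, length.out = d[1]), times = prod(d[2:3])), d)
  biased <- bp$volume
  biased@data <- bp$volume@data * (1 + 0.2 * 2 * xhat)  # +/- 20 percent
  mask <- bp$truth@labels@data > 0
  biased@data[biased@data <= 0] <- 0.1
  cb <- correctBias(biased, mask)
  wm <- bp$truth@labels@data == 3L
  cov0 <- sd(biased@data[wm]) / mean(biased@data[wm])
  cov1 <- sd(cb$corrected@data[wm]) / mean(cb$corrected@data[wm])
  expect_lt(cov1, 0.5 * cov0)
  # idempotence: a second pass changes the volume by < 1 percent RMS
  cb2 <- correctBias(cb$corrected, mask)
  relRms <- sqrt(mean((cb2$corrected@data[mask] - cb$corrected@data[mask])^2)) /
    diff(range(cb$corrected@data[mask]))
  expect_lt(relRms, 0.01)
})

test_that("bias correction validates its inputs", {
  bp <- cleanBase()
  expect_error(correctBias(bp$volume, array(FALSE, volDim(bp$volume))),
               "empty")
  mask <- bp$truth@labels@data >= 0   # includes zero-intensity background
  expect_error(correctBias(bp$volume, mask), "non-positive")
})

test_that("intensity normalisation maps into [0,100] monotonically", {
  bp <- cleanBase()
  v <- noisyVolume(bp, 4)
  n1 <- normalizeIntensity(v)
  expect_gte(min(n1@data), 0)
  expect_lte(max(n1@data), 100)
  # self-reference equals the plain linear rescale
  n2 <- normalizeIntensity(v, reference = v)
  rg <- range(v@data)
  lin <- (v@data - rg[1]) / diff(rg) * 100
  expect_equal(n2@data, lin, tolerance = 1e-6)
  # rank order is preserved
  idx <- sample(length(v@data), 4000)
  expect_equal(cor(as.numeric(n1@data)[idx], as.numeric(v@data)[idx],
                   method = "spearman"), 1)
  expect_error(normalizeIntensity(BrainVolume(array(7, c(4, 4, 4)))),
               "constant")
})

test_that("histogram matching removes a global intensity scaling", {
  bp <- cleanBase()
  v <- noisyVolume(bp, 3)
  v2 <- v
  v2@data <- v2@data * 2
  ref <- normalizeIntensity(v)
  a <- normalizeIntensity(v, reference = ref)
  b <- normalizeIntensity(v2, reference = ref)
  expect_lt(max(abs(a@data - b@data)), 1)
})

test_that("landmark rigid registration recovers known transforms", {
  bp <- cleanBase()
  lm <- bp$truth@landmarks
  # identity
  r0 <- landmarkRigid(lm, lm)
  expect_lt(max(abs(r0$transform - diag(4))), 1e-9)
  expect_lt(r0$rms, 1e-9)
  # known rotation + translation: recovers the inverse
  ang <- 10 * pi / 180
  A <- diag(4)
  A[1:2, 1:2] <- rbind(c(cos(ang), -sin(ang)), c(sin(ang), cos(ang)))
  A[1:3, 4] <- c(2, 0, 0)
  lm2 <- LandmarkSet(structure(applyTransform(A, lm@coords),
                               dimnames = dimnames(lm@coords)))
  r <- landmarkRigid(lm2, lm)
  expect_lt(max(abs(r$transform %*% A - diag(4))), 1e-6)
  # rotation block is orthonormal with det +1
  R <- r$transform[1:3, 1:3]
  expect_lt(max(abs(R %*% t(R) - diag(3))), 1e-9)
  expect_equal(det(R), 1, tolerance = 1e-9)
})

test_that("landmark jitter appears in the residual at its own scale", {
  bp <- cleanBase()
  lm <- bp$truth@landmarks
  set.seed(17)
  rms <- vapply(1:30, function(i) {
    jit <- LandmarkSet(structure(
      lm@coords + matrix(rnorm(length(lm@coords), 0, 0.5), ncol = 3),
      dimnames = dimnames(lm@coords)))
    landmarkRigid(jit, lm)$rms
  }, numeric(1))
  m <- mean(rms)
  expect_gt(m, 0.5 / 2)
  expect_lt(m, 0.5 * 2)
})

test_that("landmark registration rejects degenerate input", {
  co <- rbind(A = c(0, 0, 0), B = c(1, 0, 0), C = c(2, 0, 0))
  colin <- LandmarkSet(co)
  expect_error(landmarkRigid(colin, colin), "collinear")
  two <- LandmarkSet(co[1:2, ])
  expect_error(landmarkRigid(two, two), "3 shared")
})

test_that("AC-PC alignment fixes the stereotaxic frame", {
  # already aligned: identity, PC stays at y = -16.5
  lm <- LandmarkSet(list(AC = c(0, 0, 0), PC = c(0, -16.5, 0),
                         eye_L = c(-12, 20, -4), eye_R = c(12, 20, -4)))
  A <- acpcAlign(lm)
  expect_lt(max(abs(A - diag(4))), 1e-9)
  expect_equal(applyTransform(A, c(0, -16.5, 0))[1, ], c(0, -16.5, 0))
  # pure translation case
  lm2 <- LandmarkSet(list(AC = c(1, 2, 3), PC = c(1, -8, 3),
                          eye_L = c(-11, 22, -1), eye_R = c(13, 22, -1)))
  A2 <- acpcAlign(lm2)
  expect_equal(applyTransform(A2, c(1, 2, 3))[1, ], c(0, 0, 0))
  expect_equal(applyTransform(A2, c(1, -8, 3))[1, ], c(0, -10, 0))
  # arbitrary rotation: the AC-PC segment lands on the y axis
  ang <- 0.7
  R <- diag(4)
  R[1:3, 1:3] <- rbind(c(cos(ang), 0, sin(ang)), c(0, 1, 0),
                       c(-sin(ang), 0, cos(ang))) %*%
    rbind(c(1, 0, 0), c(0, cos(0.3), -sin(0.3)), c(0, sin(0.3), cos(0.3)))
  R[1:3, 4] <- c(4, -1, 2)
  lm3 <- LandmarkSet(structure(applyTransform(R, lm@coords),
                               dimnames = dimnames(lm@coords)))
  A3 <- acpcAlign(lm3)
  mapped <- applyTransform(A3, lm3@coords)
  expect_lt(max(abs(mapped[1, ])), 1e-9)                  # AC at origin
  expect_lt(max(abs(mapped[2, c(1, 3)])), 1e-9)           # PC on the y axis
  expect_equal(unname(mapped[2, 2]), -16.5, tolerance = 1e-9)
  expect_gt(mapped[4, 1], 0)                              # eye_R on +x
  # degenerate geometry errors
  expect_error(acpcAlign(LandmarkSet(list(AC = c(0, 0, 0), PC = c(0, -5, 0),
                                          eye_L = c(1, 1, 1),
                                          eye_R = c(1, 1, 1)))), "degenerate")
})

test_that("resampling honours its interpolation contracts", {
  bp <- cleanBase()
  v <- bp$volume
  # identity transform, same grid: exact for every order
  for (ord in c(0L, 1L, 3L, 4L)) {
    out <- resampleVolume(v, target = v, order = ord)
    expect_equal(out@data, v@data, tolerance = 1e-8)
  }
  # integer-voxel translation at order 0 is an exact shifted copy
  tr <- diag(4); tr[1, 4] <- 2
  out <- resampleVolume(v, tr, order = 0L)
  d <- volDim(v)
  expect_identical(out@data[1:(d[1] - 2), , ], v@data[3:d[1], , ])
  # half-voxel round trip on a smooth volume: max error < 1 percent of range
  sm <- smoothVolume(v, 2)
  fwd <- diag(4); fwd[1, 4] <- 1.5
  bwd <- diag(4); bwd[1, 4] <- -1.5
  interior <- bp$truth@labels@data > 0
  for (ord in c(3L, 4L)) {
    rt <- resampleVolume(resampleVolume(sm, fwd, order = ord), bwd, order = ord)
    err <- max(abs(rt@data[interior] - sm@data[interior]))
    expect_lt(err, 0.01 * diff(range(sm@data)))
  }
  expect_error(resampleVolume(v, order = 2L), "order")
})
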
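# Synthetic phantom population and cohort generator.

labelIntensity <- function(labels, classMeans) {
  lut <- c(classMeans["background"], classMeans["csf"],
           classMeans["gm"], classMeans["wm"])
  array(lut[labels + 1L], dim(labels))
}

labelVolumes_mL <- function(labels, voxvol_mm3) {
  c(csf = sum(labels == 1L), gm = sum(labels == 2L),
    wm = sum(labels == 3L)) * voxvol_mm3 / 1000
}

#' Generate the base brain phantom
#'
#' Builds a noiseless, bias-free T1w-like phantom with concentric anatomy:
#' a WM core whose boundary carries a sinusoidal "gyral" undulation, a GM
#' shell, two interior CSF ventricles, an exterior CSF rim and zero-intensity
#' background. Anatomical landmarks (AC, PC, eyes, poles, cruciate) are
#' placed deterministically from the geometry, with the AC-PC distance fixed
#' at 16.5 mm as in the adult ovine brain.
#'
#' @param spec a [PhantomSpec-class].
#' @return List with elements `volume` ([BrainVolume-class]) and
#'   `truth` ([GroundTruth-class]).
#' @export
makeBasePhantom <- function(spec) {
  validObject(spec)
  d <- spec@gridShape
  vs <- spec@voxelSize
  half <- vs * (d - 1) / 2
  # brain semi-axes shrink with the grid so smaller test grids stay valid
  ax <- pmin(spec@brainAxes, 0.64 * half)
  if (any(ax < 6)) stop("grid too small to contain all phantom compartments")
  xs <- seq(-half[1], half[1], by = vs)
  ys <- seq(-half[2], half[2], by = vs)
  zs <- seq(-half[3], half[3], by = vs)
  X <- array(rep(xs, times = d[2] * d[3]), d)
  Y <- array(rep(rep(ys, each = d[1]), times = d[3]), d)
  Z <- array(rep(zs, each = d[1] * d[2]), d)
  rho <- sqrt((X / ax[1])^2 + (Y / ax[2])^2 + (Z / ax[3])^2)
  r3 <- pmax(sqrt(X^2 + Y^2 + Z^2), 1e-9)
  theta <- atan2(Y, X)
  phi <- acos(pmin(pmax(Z / r3, -1), 1))
  amp <- spec@gyralAmplitude
  gOuter <- 1 + amp * sin(5 * theta) * sin(4 * phi)
  gInner <- 1 + amp * sin(7 * theta + 1) * sin(5 * phi + 0.5)
  labels <- array(0L, d)
  labels[rho <= 1] <- 1L                          # exterior CSF rim
  labels[rho <= spec@gmRadius * gOuter] <- 2L     # GM shell
  labels[rho <= spec@wmRadius * gInner] <- 3L     # WM core
  sc <- min(ax / spec@brainAxes)
  if (spec@ventricles) {
    # two CSF ellipsoids carved into the WM core
    vrad <- c(2.5, 6, 2.5) * sc
    for (sgn in c(-1, 1)) {
      ctr <- c(sgn * 4, 2, 0) * sc
      vv <- ((X - ctr[1]) / vrad[1])^2 + ((Y - ctr[2]) / vrad[2])^2 +
        ((Z - ctr[3]) / vrad[3])^2
      labels[vv <= 1 & labels == 3L] <- 1L
    }
  }
  vol <- BrainVolume(labelIntensity(labels, spec@classMeans), spacing = vs)
  lms <- LandmarkSet(list(
    AC = c(0, 6, -2) * sc,
    PC = c(0, 6 - 16.5, -2) * sc,    # AC-PC distance 16.5 mm at full scale
    eye_L = c(-12, 24, -4) * sc,
    eye_R = c(12, 24, -4) * sc,
    pole_rostral = c(0, 0.9 * ax[2], 0),
    pole_caudal = c(0, -0.9 * ax[2], 0),
    cruciate = c(0, 10, 12) * sc))
  truth <- new("GroundTruth",
               labels = BrainVolume(labels, affine = vol@affine),
               landmarks = lms, trueTransform = NULL,
               trueVolumes = labelVolumes_mL(labels, vs^3))
  list(volume = vol, truth = truth)
}

# smooth random displacement field with |u| <= amplitude, by Gaussian
# smoothing of white noise and rescaling; folding handled by the caller
randomField <- function(gdim, affine, amplitude_mm, smooth_mm, spacing) {
  u <- array(stats::rnorm(prod(gdim) * 3), c(gdim, 3L))
  sig_vox <- rep_len(smooth_mm, 3L) / spacing
  for (cmp in 1:3)
    u[, , , cmp] <- array(cpp_gauss_smooth(as.numeric(u[, , , cmp]),
                                           as.integer(gdim), sig_vox), gdim)
  mag <- sqrt(u[, , , 1]^2 + u[, , , 2]^2 + u[, , , 3]^2)
  u <- u * (amplitude_mm / max(mag, 1e-12))
  new("DisplacementField", field = u, affine = affine)
}

# smooth multiplicative bias field in [1-a, 1+a]
randomBias <- function(gdim, spacing, amplitude, smooth_mm = 20) {
  b <- array(stats::rnorm(prod(gdim)), gdim)
  b <- array(cpp_gauss_smooth(as.numeric(b), as.integer(gdim),
                              rep_len(smooth_mm, 3L) / spacing), gdim)
  b <- b / max(abs(b), 1e-12) * amplitude
  1 + b
}

#' Derive a subject phantom from the base phantom
#'
#' Applies a random similarity transform (rotations up to 10 degrees,
#' translations up to 5 mm, isotropic scale 0.9-1.1) composed with a smooth
#' random displacement field, then a multiplicative bias field and additive
#' noise. The ground truth carries the exact composite transform (mapping
#' subject world coordinates to base world coordinates) and the warped
#' labels. Fields whose Jacobian determinant is not everywhere positive are
#' rejected and regenerated at reduced amplitude (error after 10 attempts).
#'
#' @param base result of [makeBasePhantom()].
#' @param spec the [PhantomSpec-class] controlling artefact levels.
#' @param subject_seed integer seed for this subject's randomness.
#' @param similarity optional 4x4 matrix overriding the random similarity
#'   transform (e.g. `diag(4)` for an artefact-only subject).
#' @return List with `volume`, `truth` and `id`.
#' @export
makeSubject <- function(base, spec, subject_seed, similarity = NULL) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(subject_seed))
  d <- volDim(base$volume)
  vs <- voxelSize(base$volume)
  # similarity transform about the world origin (volume centre)
  rot <- stats::runif(3, -10, 10) * pi / 180
  trn <- stats::runif(3, -5, 5)
  scl <- stats::runif(1, 0.9, 1.1)
  R <- rotZ(rot[3]) %*% rotY(rot[2]) %*% rotX(rot[1])
  A <- diag(4)
  A[1:3, 1:3] <- R * scl
  A[1:3, 4] <- trn
  if (!is.null(similarity)) A <- similarity
  # subject(x) = base(t(x)); t = A (x + u(x)) maps subject world -> base world
  amp <- spec@deformAmplitude
  fld <- NULL
  if (amp > 0) {
    for (attempt in 1:10) {
      fld <- randomField(d, base$volume@affine, amp, spec@deformSmoothness, vs)
      if (min(fieldJacobian(fld)) > 0.05) break
      amp <- amp * 0.7
      fld <- NULL
    }
    if (is.null(fld)) stop("could not generate a fold-free displacement field")
  }
  chain <- TransformChain(A, field = fld)
  vol <- resampleVolume(base$volume, chain, target = base$volume, order = 1L)
  labels <- resampleVolume(base$truth@labels, chain, target = base$volume,
                           order = 0L)
  labels@data <- array(as.integer(round(labels@data)), d)
  img <- vol@data
  if (spec@biasAmplitude > 0)
    img <- img * randomBias(d, vs, spec@biasAmplitude)
  if (spec@noiseSd > 0) {
    if (spec@noiseModel == "rician") {
      img <- sqrt((img + stats::rnorm(length(img), 0, spec@noiseSd))^2 +
                    stats::rnorm(length(img), 0, spec@noiseSd)^2)
    } else {
      img <- img + stats::rnorm(length(img), 0, spec@noiseSd)
    }
  }
  vol@data <- array(img, d)
  lmw <- base$truth@landmarks@coords
  inv <- invertTransform(chain, grid = base$volume)
  lms <- LandmarkSet(structure(applyTransform(inv, lmw),
                               dimnames = dimnames(lmw)))
  truth <- new("GroundTruth", labels = labels, landmarks = lms,
               trueTransform = chain,
               trueVolumes = labelVolumes_mL(labels@data, prod(vs)))
  list(volume = vol, truth = truth, id = sprintf("subj%03d", subject_seed))
}

#' Generate a phantom population
#'
#' Convenience wrapper building the base phantom and `n` derived subjects
#' with seeds `spec@seed * 1000 + 1:n`.
#'
#' @param spec a [PhantomSpec-class].
#' @param n number of subjects.
#' @return List with `base` and `subjects` (list of [makeSubject()] results).
#' @export
makePopulation <- function(spec, n) {
  base <- makeBasePhantom(spec)
  subjects <- lapply(seq_len(n), function(i)
    makeSubject(base, spec, spec@seed * 1000L + i))
  names(subjects) <- vapply(subjects, `[[`, character(1), "id")
  list(base = base, subjects = subjects)
}

rotX <- function(a) rbind(c(1, 0, 0), c(0, cos(a), -sin(a)), c(0, sin(a), cos(a)))
rotY <- function(a) rbind(c(cos(a), 0, sin(a)), c(0, 1, 0), c(-sin(a), 0, cos(a)))
rotZ <- function(a) rbind(c(cos(a), -sin(a), 0), c(sin(a), cos(a), 0), c(0, 0, 1))

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

# Gauss hypergeometric 2F1(1, 1; c; x) by series (0 <= x < 1)
hyp2f1_11 <- function(c, x) {
  term <- 1; s <- 1
  for (k in 1:2000) {
    term <- term * k / (c + k - 1) * x
    s <- s + term
    if (abs(term) < 1e-14 * abs(s)) break
  }
  s
}

# E[r^2] for a sample (partial) correlation of population value rho2 whose
# t-statistic has df residual degrees of freedom (effective sample m = df+2)
expectedR2 <- function(rho2, df) {
  m <- df + 2
  1 - (1 - rho2) * (m - 2) / (m - 1) * hyp2f1_11((m + 1) / 2, rho2)
}

# invert expectedR2: population rho2 whose expected sample estimate is target
calibratePartialVar <- function(target, df) {
  if (target <= 0) return(0)
  base <- expectedR2(0, df)
  if (target <= base) return(0)
  stats::uniroot(function(r) expectedR2(r, df) - target,
                 c(1e-10, 1 - 1e-8), tol = 1e-12)$root
}

#' Simulate a cohort demographic and volume table
#'
#' Samples body weight and age from zero-truncated normals, assigns sex by
#' the requested counts, and constructs tissue volumes with the generating
#' effect structure: GM carries a body-weight effect, WM an age effect, CSF
#' is independent noise about its base volume. Residual noise is calibrated
#' so that the sex + age + body-weight linear model's partial explained
#' variance, averaged over replicate cohorts of this size, recovers the
#' requested value (the printed cohort estimates being finite-sample
#' statistics themselves; see the methods vignette).
#'
#' @param cspec a [CohortSpec-class].
#' @return A `data.frame` with columns `subject_id, sex, age_months, bw_kg,
#'   gm_mL, wm_mL, csf_mL`.
#' @export
makeCohort <- function(cspec) {
  validObject(cspec)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(cspec@seed)
  n <- cspec@nSubjects
  rtnorm <- function(n, m, s) {
    x <- stats::rnorm(n, m, s)
    while (any(x <= 0)) x[x <= 0] <- stats::rnorm(sum(x <= 0), m, s)
    x
  }
  bw <- rtnorm(n, cspec@bwMean, cspec@bwSd)
  age <- rtnorm(n, cspec@ageMean, cspec@ageSd)
  sex <- rep(c("male", "female"), c(cspec@sexCounts["male"],
                                    cspec@sexCounts["female"]))
  # partial correlation of one covariate given the 2 others: the estimate
  # behaves as an ordinary correlation at effective sample size n - 2,
  # i.e. t-statistic df = n - 4
  df <- n - 4L
  # GM: given effect size, calibrate residual SD to the partial variance
  pGM <- calibratePartialVar(cspec@partialVarBwGm, df)
  bGM <- cspec@effectBwOnGm
  if (pGM > 0 && bGM == 0)
    stop("cannot realise a nonzero partial variance with a zero effect")
  sdGM <- if (pGM > 0) abs(bGM) * cspec@bwSd * sqrt((1 - pGM) / pGM) else 4.4
  bGMeff <- if (pGM > 0) bGM else 0
  gm <- cspec@baseVolumes["gm"] + bGMeff * (bw - cspec@bwMean) +
    stats::rnorm(n, 0, sdGM)
  # WM: given residual SD, calibrate the age effect to the partial variance
  pWM <- calibratePartialVar(cspec@partialVarAgeWm, df)
  bAge <- if (pWM > 0) sqrt(pWM / (1 - pWM)) * cspec@wmSd / cspec@ageSd else 0
  wm <- cspec@baseVolumes["wm"] + bAge * (age - cspec@ageMean) +
    stats::rnorm(n, 0, cspec@wmSd)
  csf <- cspec@baseVolumes["csf"] + stats::rnorm(n, 0, cspec@csfSd)
  data.frame(subject_id = sprintf("s%03d", seq_len(n)),
             sex = sex, age_months = age, bw_kg = bw,
             gm_mL = unname(gm), wm_mL = unname(wm), csf_mL = unname(csf),
             stringsAsFactors = FALSE)
}
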
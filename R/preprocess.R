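# Per-subject preprocessing: bias correction, intensity normalisation,
# landmark-based rigid initialisation and AC-PC alignment.

# monomial design matrix for a 3D polynomial of the given total order,
# on coordinates normalised to [-1, 1]
polyDesign <- function(pts01, order) {
  cols <- list(rep(1, nrow(pts01)))
  for (a in 0:order) for (b in 0:(order - a)) for (cc in 0:(order - a - b)) {
    if (a + b + cc == 0) next
    cols[[length(cols) + 1L]] <- pts01[, 1]^a * pts01[, 2]^b * pts01[, 3]^cc
  }
  do.call(cbind, cols)
}

#' Smooth multiplicative bias-field correction
#'
#' Estimates a smooth multiplicative intensity inhomogeneity field by
#' fitting a low-order 3D polynomial to log intensities inside the mask,
#' after removing the tissue-class structure (a deterministic 3-class
#' intensity classification, re-estimated each iteration). The field is
#' normalised to mean 1 over the mask and divided out. This is a
#' self-contained smooth-field estimator in the spirit of classical
#' log-domain inhomogeneity correction.
#'
#' @param v a [BrainVolume-class]; intensities must be positive inside the mask.
#' @param brain_mask logical/0-1 array matching `v` (non-empty).
#' @param order polynomial order of the field model (default 3).
#' @param iterations classification/fit refinement iterations.
#' @return List with `corrected` ([BrainVolume-class]) and `bias_field`
#'   ([BrainVolume-class], mean 1 inside the mask).
#' @export
correctBias <- function(v, brain_mask, order = 3L, iterations = 3L) {
  mask <- as.logical(brain_mask)
  if (!any(mask)) stop("mask is empty")
  img <- v@data
  if (any(img[mask] <= 0)) stop("non-positive intensities inside mask")
  d <- volDim(v)
  idx <- which(mask)
  # voxel coordinates normalised to [-1, 1]
  ijk <- arrayInd(idx, d)
  pts01 <- sweep(sweep(ijk - 1, 2, (d - 1) / 2, `-`), 2, (d - 1) / 2, `/`)
  X <- polyDesign(pts01, order)
  logv <- log(img[idx])
  logfield <- rep(0, length(idx))
  for (it in seq_len(iterations)) {
    resid <- logv - logfield
    # deterministic 3-class split of the corrected log intensities
    cuts <- stats::quantile(resid, c(1, 2) / 3)
    cl <- findInterval(resid, cuts) + 1L
    for (km in 1:10) {
      mu <- vapply(1:3, function(k) mean(resid[cl == k]), numeric(1))
      mu[!is.finite(mu)] <- range(resid)[c(1, 2)][1]
      ncl <- apply(abs(outer(resid, mu, `-`)), 1, which.min)
      if (all(ncl == cl)) break
      cl <- ncl
    }
    clmean <- ave(resid, cl)
    fit <- stats::lm.fit(X, logv - clmean)
    logfield <- X %*% fit$coefficients
    logfield <- logfield - mean(logfield)
  }
  field <- array(1, d)
  field[idx] <- exp(logfield)
  field[idx] <- field[idx] / mean(field[idx])
  corrected <- img
  corrected[idx] <- img[idx] / field[idx]
  list(corrected = BrainVolume(corrected, affine = v@affine),
       bias_field = BrainVolume(field, affine = v@affine))
}

#' Linear 0-100 normalisation with optional histogram matching
#'
#' Linearly rescales intensities to \[0, 100\]; if a reference volume is
#' given, the empirical CDF of the rescaled input is then matched to the
#' reference's via a monotone 256-bin lookup with linear interpolation.
#'
#' @param v input [BrainVolume-class] (non-constant intensities).
#' @param reference optional reference [BrainVolume-class].
#' @param nbins number of histogram bins for matching.
#' @return Normalised [BrainVolume-class] with values in \[0, 100\].
#' @export
normalizeIntensity <- function(v, reference = NULL, nbins = 256L) {
  x <- as.numeric(v@data)
  rg <- range(x)
  if (diff(rg) == 0) stop("constant input intensities")
  x <- (x - rg[1]) / diff(rg) * 100
  if (!is.null(reference)) {
    r <- as.numeric(reference@data)
    rrg <- range(r)
    if (diff(rrg) == 0) stop("constant reference intensities")
    r <- (r - rrg[1]) / diff(rrg) * 100
    qs <- seq(0, 1, length.out = nbins)
    xq <- stats::quantile(x, qs, names = FALSE, type = 7)
    rq <- stats::quantile(r, qs, names = FALSE, type = 7)
    # monotone lookup input-quantile -> reference-quantile
    xq <- cummax(xq); rq <- cummax(rq)
    x <- stats::approx(xq, rq, xout = x, rule = 2, ties = "ordered")$y
    x <- pmin(pmax(x, 0), 100)
  }
  BrainVolume(array(x, volDim(v)), affine = v@affine)
}

sharedLandmarks <- function(moving, fixed) {
  nm <- intersect(rownames(moving@coords), rownames(fixed@coords))
  if (length(nm) < 3L) stop("need at least 3 shared landmarks")
  list(m = moving@coords[nm, , drop = FALSE],
       f = fixed@coords[nm, , drop = FALSE], names = nm)
}

#' Least-squares rigid landmark registration (Procrustes, no scaling)
#'
#' Finds the rigid transform T minimising the sum of squared distances
#' between `T(moving)` and `fixed` over the shared landmark names, via the
#' SVD (Kabsch) solution with a proper-rotation constraint.
#'
#' @param moving,fixed [LandmarkSet-class] objects with >= 3 shared,
#'   non-collinear names.
#' @return List with `transform` (4x4 rigid matrix, det +1) and
#'   `rms` (residual root-mean-square distance, mm).
#' @export
landmarkRigid <- function(moving, fixed) {
  s <- sharedLandmarks(moving, fixed)
  mC <- colMeans(s$m); fC <- colMeans(s$f)
  M <- sweep(s$m, 2, mC); F <- sweep(s$f, 2, fC)
  sv <- svd(t(M) %*% F)
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1e-300))
    stop("landmarks are collinear")
  D <- diag(c(1, 1, sign(det(sv$v %*% t(sv$u)))))
  R <- sv$v %*% D %*% t(sv$u)
  t_vec <- fC - R %*% mC
  A <- diag(4); A[1:3, 1:3] <- R; A[1:3, 4] <- t_vec
  resid <- t(R %*% t(s$m) + as.numeric(t_vec)) - s$f
  list(transform = A, rms = sqrt(mean(rowSums(resid^2))))
}

#' AC-PC alignment transform
#'
#' Constructs the rigid transform into stereotaxic space: AC maps to the
#' origin, PC to (0, -d, 0) with d the AC-PC distance (so +y is rostral),
#' the left-right eye axis defines +x (right), and +z is dorsal, following
#' the MNI-like convention.
#'
#' @param lm a [LandmarkSet-class] containing AC, PC and eye_L/eye_R.
#' @return 4x4 rigid matrix mapping input world coordinates to AC-PC space.
#' @export
acpcAlign <- function(lm) {
  co <- lm@coords
  need <- c("AC", "PC")
  if (!all(need %in% rownames(co))) stop("AC and PC landmarks required")
  if (!all(c("eye_L", "eye_R") %in% rownames(co)))
    stop("a lateral pair (eye_L/eye_R) is required")
  ac <- co["AC", ]; pc <- co["PC", ]
  yv <- ac - pc
  dy <- sqrt(sum(yv^2))
  if (dy < 1e-9) stop("degenerate geometry: AC equals PC")
  yv <- yv / dy
  xv <- co["eye_R", ] - co["eye_L", ]
  if (sqrt(sum(xv^2)) < 1e-9) stop("degenerate geometry: eyes coincide")
  xv <- xv - sum(xv * yv) * yv
  nx <- sqrt(sum(xv^2))
  if (nx < 1e-9) stop("degenerate geometry: eye axis parallel to AC-PC")
  xv <- xv / nx
  zv <- c(xv[2] * yv[3] - xv[3] * yv[2],
          xv[3] * yv[1] - xv[1] * yv[3],
          xv[1] * yv[2] - xv[2] * yv[1])
  R <- rbind(xv, yv, zv)
  A <- diag(4)
  A[1:3, 1:3] <- R
  A[1:3, 4] <- -R %*% ac
  dimnames(A) <- NULL
  A
}
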
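# Intensity-based rigid/affine registration (NCC, multi-resolution local
# search) and demons-style non-linear registration (SSD forces, Gaussian
# fluid/diffusion regularisation).

paramsToAffine <- function(p, centre, dof) {
  rot <- p[1:3] * pi / 180
  R <- rotZ(rot[3]) %*% rotY(rot[2]) %*% rotX(rot[1])
  L <- R
  if (dof == 12L) {
    S <- diag(exp(p[7:9]))
    H <- diag(3); H[1, 2] <- p[10]; H[1, 3] <- p[11]; H[2, 3] <- p[12]
    L <- R %*% S %*% H
  }
  A <- diag(4)
  A[1:3, 1:3] <- L
  A[1:3, 4] <- p[4:6] + centre - L %*% centre
  A
}

nccSimilarity <- function(fixedVals, movingVals) {
  keep <- is.finite(movingVals)
  f <- fixedVals[keep]; m <- movingVals[keep]
  sf <- stats::sd(f); sm <- stats::sd(m)
  if (sf == 0 || sm == 0) return(0)
  mean((f - mean(f)) * (m - mean(m))) / (sf * sm)
}

#' Linear (rigid or affine) intensity-based registration
#'
#' Maximises the normalised cross-correlation between the fixed volume and
#' the moving volume resampled through a rigid (6 dof) or full affine
#' (12 dof: rotations, translations, log-scales, shears) transform, using
#' multi-resolution (4x / 2x / 1x) Nelder-Mead local search about `init`.
#' The transform maps fixed world coordinates to moving world coordinates.
#'
#' @param moving,fixed [BrainVolume-class] volumes with comparable
#'   intensity ranges (normalise first).
#' @param dof 6 (rigid) or 12 (affine).
#' @param init optional 4x4 initial transform (identity default).
#' @param levels integer downsampling factors, coarse to fine.
#' @param maxit Nelder-Mead iteration cap, recycled per level.
#' @return List with `transform` (4x4), `similarity` (final NCC at full
#'   resolution), `initial_similarity` (NCC of `init` at full resolution),
#'   and `trace` (per-level NCC).
#' @export
registerLinear <- function(moving, fixed, dof = 6L, init = diag(4),
                           levels = c(4L, 2L, 1L),
                           maxit = c(300L, 200L, 120L)) {
  dof <- as.integer(dof)
  if (!dof %in% c(6L, 12L)) stop("dof must be 6 or 12")
  maxit <- rep_len(as.integer(maxit), length(levels))
  centre <- as.numeric(indexToWorld(fixed, matrix((volDim(fixed) - 1) / 2, 1)))
  # expressing init in parameters is not unique; optimise a correction C
  # about init instead: T = init %*% C(p)
  npar <- if (dof == 6L) 6L else 12L
  p <- rep(0, npar)
  scale <- c(rep(2, 3), rep(2, 3), rep(0.05, 3), rep(0.05, 3))[1:npar]
  trace <- list()
  objAt <- function(fx, mv) {
    d <- volDim(mv)
    coeff <- as.numeric(mv@data)
    fvals <- as.numeric(fx@data)
    Ain_inv <- solve(mv@affine)
    Aout <- fx@affine
    function(pp) {
      A <- init %*% paramsToAffine(pp, centre, dof)
      M <- Ain_inv %*% A %*% Aout
      vals <- cpp_sample_affine(coeff, as.integer(d), M[1:3, , drop = FALSE],
                                as.integer(volDim(fx)), 1L)
      -nccSimilarity(fvals, vals)
    }
  }
  objFine <- objAt(fixed, moving)
  init_sim <- -objFine(rep(0, npar))
  for (li in seq_along(levels)) {
    lv <- levels[li]
    obj <- if (lv == 1L) objFine
    else objAt(downsampleVolume(fixed, lv), downsampleVolume(moving, lv))
    opt <- stats::optim(p, obj, method = "Nelder-Mead",
                        control = list(maxit = maxit[li], parscale = scale,
                                       reltol = 1e-9))
    if (opt$value <= obj(p)) p <- opt$par
    trace[[length(trace) + 1L]] <- list(level = lv, ncc = -opt$value)
  }
  final <- -objFine(p)
  if (final < init_sim) {
    # a coarse-level optimum that does not improve the full-resolution
    # similarity is discarded in favour of the initialisation
    p <- rep(0, npar)
    final <- init_sim
  }
  if (final < init_sim - 0.05)
    stop(sprintf("registration diverged: NCC %.4f -> %.4f", init_sim, final))
  list(transform = init %*% paramsToAffine(p, centre, dof),
       similarity = final, initial_similarity = init_sim, trace = trace)
}

#' Demons-style non-linear registration
#'
#' Coarse-to-fine demons iteration: at each schedule stage the volumes are
#' represented at roughly `step_mm` resolution, and each iteration applies an
#' SSD-gradient force, Gaussian fluid smoothing of the force at scale
#' `step_mm`, a field update, and Gaussian diffusion smoothing of the field
#' at `step_mm / 2`. Inputs must be linearly pre-aligned on a common grid.
#' The returned field `u` (world mm, on the fixed grid) satisfies
#' `moving(x + u(x)) ~ fixed(x)`.
#'
#' @param moving,fixed pre-aligned [BrainVolume-class] volumes on the same grid.
#' @param schedule list of `c(step_mm, n_iter)` pairs, coarse to fine
#'   (default 4 iterations each at 4, 2 and 1 mm).
#' @param inner demons update sub-steps per schedule iteration (each
#'   schedule iteration is a full optimisation pass at its scale).
#' @return List with `field` ([DisplacementField-class]), `ssd_trace`
#'   (mean squared difference before and after every stage), and
#'   `fold_fraction` (fraction of voxels with non-positive Jacobian).
#' @export
registerNonlinear <- function(moving, fixed,
                              schedule = list(c(4, 4), c(2, 4), c(1, 4)),
                              inner = 8L) {
  if (!all(volDim(moving) == volDim(fixed)))
    stop("moving and fixed must share a grid (linearly pre-align first)")
  vs <- voxelSize(fixed)
  dfull <- volDim(fixed)
  u <- NULL   # field on current working grid
  ssd_of <- function(mv, fx, uu) {
    g <- list(dim = volDim(fx), affine = fx@affine)
    x <- worldGrid(fx)
    idx <- worldToIndex(mv, x + uu)
    w <- cpp_sample(as.numeric(mv@data), as.integer(volDim(mv)), idx, 1L)
    mean((w - as.numeric(fx@data))^2)
  }
  trace <- list()
  for (st in schedule) {
    step <- st[1]; nit <- st[2]
    fac <- max(1L, as.integer(round(step / max(vs))))
    fx <- downsampleVolume(fixed, fac)
    mv <- downsampleVolume(moving, fac)
    gdim <- volDim(fx)
    x <- worldGrid(fx)
    # carry field over from the previous stage (resample onto this grid)
    if (is.null(u)) {
      uu <- matrix(0, nrow(x), 3)
    } else {
      uu <- sampleField(u, x)
    }
    fvals <- as.numeric(fx@data)
    spc <- voxelSize(fx)
    Ainv <- solve(mv@affine)
    ssd0 <- NA_real_
    n1 <- gdim[1]; n2 <- gdim[2]; n3 <- gdim[3]
    grad3 <- function(arr) {
      g <- list(array(0, gdim), array(0, gdim), array(0, gdim))
      g[[1]][2:(n1 - 1), , ] <- (arr[3:n1, , ] - arr[1:(n1 - 2), , ]) / (2 * spc[1])
      g[[2]][, 2:(n2 - 1), ] <- (arr[, 3:n2, ] - arr[, 1:(n2 - 2), ]) / (2 * spc[2])
      g[[3]][, , 2:(n3 - 1)] <- (arr[, , 3:n3] - arr[, , 1:(n3 - 2)]) / (2 * spc[3])
      g
    }
    gf <- grad3(array(fvals, gdim))
    for (it in seq_len(nit * inner)) {
      idx <- t(Ainv[1:3, 1:3] %*% t(x + uu) + Ainv[1:3, 4])
      w <- cpp_sample(as.numeric(mv@data), as.integer(volDim(mv)), idx, 1L)
      diffv <- w - fvals
      if (it == 1L) ssd0 <- mean(diffv^2)
      # symmetric force: mean of fixed and warped-moving gradients
      gw <- grad3(array(w, gdim))
      gx <- (as.numeric(gw[[1]]) + as.numeric(gf[[1]])) / 2
      gy <- (as.numeric(gw[[2]]) + as.numeric(gf[[2]])) / 2
      gz <- (as.numeric(gw[[3]]) + as.numeric(gf[[3]])) / 2
      g2 <- gx^2 + gy^2 + gz^2
      denom <- g2 + diffv^2 / step^2
      f <- -diffv / pmax(denom, 1e-8)
      force <- cbind(f * gx, f * gy, f * gz)
      # fluid smoothing of the force, then update, then diffusion smoothing
      for (cmp in 1:3)
        force[, cmp] <- cpp_gauss_smooth(force[, cmp], as.integer(gdim),
                                         0.5 * step / spc)
      uu <- uu + force
      for (cmp in 1:3)
        uu[, cmp] <- cpp_gauss_smooth(uu[, cmp], as.integer(gdim),
                                      0.5 * step / spc)
    }
    idx <- t(Ainv[1:3, 1:3] %*% t(x + uu) + Ainv[1:3, 4])
    w <- cpp_sample(as.numeric(mv@data), as.integer(volDim(mv)), idx, 1L)
    trace[[length(trace) + 1L]] <- list(step_mm = step, ssd_before = ssd0,
                                        ssd_after = mean((w - fvals)^2))
    u <- new("DisplacementField", field = array(uu, c(gdim, 3L)),
             affine = fx@affine)
  }
  # tabulate the final field on the full-resolution fixed grid
  xf <- worldGrid(fixed)
  uf <- sampleField(u, xf)
  field <- new("DisplacementField", field = array(uf, c(dfull, 3L)),
               affine = fixed@affine)
  jac <- fieldJacobian(field)
  fold <- mean(jac <= 0)
  if (fold > 0.01)
    warning(sprintf("displacement field folds on %.1f%% of voxels",
                    100 * fold))
  list(field = field, ssd_trace = trace, fold_fraction = fold)
}
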
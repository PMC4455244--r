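# Volume resampling through transform chains (pull-back convention).

asGrid <- function(target) {
  if (is(target, "BrainVolume"))
    return(list(dim = volDim(target), affine = target@affine))
  if (is.list(target) && all(c("dim", "affine") %in% names(target)))
    return(list(dim = as.integer(target$dim), affine = target$affine))
  stop("target must be a BrainVolume or list(dim=, affine=)")
}

#' Resample a volume through a transform
#'
#' Pull-back resampling: each target voxel takes the value of the source
#' volume at `t(x)`, i.e. `out(x) = v(t(x))`. Interpolation uses B-splines
#' of the requested order (with the interpolating prefilter for orders
#' >= 2); points falling outside the source field of view are set to 0.
#'
#' @param v source [BrainVolume-class].
#' @param transform a [TransformChain-class] or 4x4 world matrix mapping
#'   target world coordinates to source world coordinates (identity default).
#' @param target target grid: a [BrainVolume-class] or `list(dim=, affine=)`.
#' @param order interpolation order, one of 0 (nearest), 1 (trilinear),
#'   3 or 4 (B-spline).
#' @return [BrainVolume-class] on the target grid.
#' @export
resampleVolume <- function(v, transform = TransformChain(), target = v,
                           order = 1L) {
  order <- as.integer(order)
  if (!order %in% c(0L, 1L, 3L, 4L))
    stop("order must be one of 0, 1, 3, 4")
  if (is.matrix(transform)) transform <- TransformChain(transform)
  g <- asGrid(target)
  d <- volDim(v)
  coeff <- if (order >= 2L)
    cpp_prefilter(as.numeric(v@data), as.integer(d), order)
  else as.numeric(v@data)
  Ain_inv <- solve(v@affine)
  if (is.null(transform@field)) {
    M <- Ain_inv %*% transform@affine %*% g$affine
    vals <- cpp_sample_affine(coeff, as.integer(d), M[1:3, , drop = FALSE],
                              as.integer(g$dim), order)
  } else {
    x <- worldGrid(BrainVolume(array(0, g$dim), affine = g$affine))
    src <- applyTransform(transform, x)
    idx <- t(Ain_inv[1:3, 1:3] %*% t(src) + Ain_inv[1:3, 4])
    vals <- cpp_sample(coeff, as.integer(d), idx, order)
  }
  BrainVolume(array(vals, g$dim), affine = g$affine)
}

#' Jacobian determinant of Id + field
#'
#' Central-difference Jacobian determinant of the mapping
#' `x -> x + u(x)` on the field's own grid, used to check displacement
#' fields for folding.
#'
#' @param field a [DisplacementField-class].
#' @return 3D array of determinant values.
#' @export
fieldJacobian <- function(field) {
  u <- field@field
  d <- dim(u)[1:3]
  sp <- sqrt(colSums(field@affine[1:3, 1:3]^2))
  # partial derivative of component c along axis a (world mm per mm)
  dd <- function(comp, ax) {
    arr <- u[, , , comp]
    up <- arr; dn <- arr
    n <- d[ax]
    idx1 <- c(2:n, n); idx0 <- c(1, 1:(n - 1))
    if (ax == 1) { up <- arr[idx1, , , drop = FALSE]; dn <- arr[idx0, , , drop = FALSE] }
    if (ax == 2) { up <- arr[, idx1, , drop = FALSE]; dn <- arr[, idx0, , drop = FALSE] }
    if (ax == 3) { up <- arr[, , idx1, drop = FALSE]; dn <- arr[, , idx0, drop = FALSE] }
    den <- array(2, d); # central everywhere except one-sided at edges
    if (ax == 1) { den[1, , ] <- 1; den[n, , ] <- 1 }
    if (ax == 2) { den[, 1, ] <- 1; den[, n, ] <- 1 }
    if (ax == 3) { den[, , 1] <- 1; den[, , n] <- 1 }
    (up - dn) / (den * sp[ax])
  }
  J11 <- 1 + dd(1, 1); J12 <- dd(1, 2); J13 <- dd(1, 3)
  J21 <- dd(2, 1); J22 <- 1 + dd(2, 2); J23 <- dd(2, 3)
  J31 <- dd(3, 1); J32 <- dd(3, 2); J33 <- 1 + dd(3, 3)
  J11 * (J22 * J33 - J23 * J32) - J12 * (J21 * J33 - J23 * J31) +
    J13 * (J21 * J32 - J22 * J31)
}
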
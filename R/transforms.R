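# Transform algebra: application, composition, inversion, log-Euclidean means.

# matrix square root by Denman-Beavers iteration (valid for proper affines,
# which have no eigenvalues on the closed negative real axis)
matSqrt <- function(A) {
  Y <- A
  Z <- diag(nrow(A))
  for (i in 1:60) {
    Yn <- (Y + solve(Z)) / 2
    Zn <- (Z + solve(Y)) / 2
    if (max(abs(Yn - Y)) < 1e-14) { Y <- Yn; break }
    Y <- Yn; Z <- Zn
  }
  Y
}

# principal matrix logarithm by inverse scaling-and-squaring + Mercator
# series (robust for defective matrices such as pure translations)
matLog <- function(A) {
  if (abs(det(A)) < 1e-12) stop("singular matrix has no logarithm")
  k <- 0L
  I <- diag(nrow(A))
  while (max(abs(A - I)) > 0.25 && k < 40L) {
    A <- matSqrt(A)
    k <- k + 1L
  }
  X <- A - I
  S <- X
  P <- X
  for (m in 2:30) {
    P <- P %*% X
    S <- S + (-1)^(m + 1) * P / m
  }
  S * 2^k
}

# matrix exponential by scaling-and-squaring + Taylor series
matExp <- function(A) {
  nrm <- max(abs(A))
  s <- max(0L, ceiling(log2(max(nrm, 1e-16))) + 1L)
  A <- A / 2^s
  E <- diag(nrow(A))
  P <- diag(nrow(A))
  for (m in 1:16) {
    P <- P %*% A / m
    E <- E + P
  }
  for (i in seq_len(s)) E <- E %*% E
  E
}

# sample a displacement field (world mm) at world points; zero outside
sampleField <- function(field, pts_world) {
  idx <- worldToIndex(field@affine, pts_world)
  d <- dim(field@field)
  vapply(1:3, function(cmp)
    cpp_sample(as.numeric(field@field[, , , cmp]), as.integer(d[1:3]), idx, 1L),
    numeric(nrow(pts_world)))
}

#' Apply a transform to world points
#'
#' Evaluates `t(x) = A (x + u(x))` for an n x 3 matrix of world points.
#'
#' @param transform a [TransformChain-class] or plain 4x4 matrix.
#' @param pts n x 3 matrix of world coordinates (mm).
#' @return n x 3 matrix of mapped coordinates.
#' @export
applyTransform <- function(transform, pts) {
  if (is.matrix(transform)) transform <- TransformChain(transform)
  if (is.vector(pts)) pts <- matrix(pts, ncol = 3)
  if (!is.null(transform@field))
    pts <- pts + sampleField(transform@field, pts)
  t(transform@affine[1:3, 1:3] %*% t(pts) + transform@affine[1:3, 4])
}

#' Invert an affine transform
#'
#' @param a 4x4 matrix or affine-only [TransformChain-class].
#' @return Object of the same kind holding the exact inverse.
#' @export
invertAffine <- function(a) {
  if (is.matrix(a)) return(solve(a))
  if (!is.null(a@field))
    stop("invertAffine is exact for affine transforms only; use invertTransform")
  TransformChain(solve(a@affine))
}

#' Invert a transform chain (numerically, when a field is present)
#'
#' The affine part is inverted exactly; the displacement field inverse is
#' obtained by fixed-point iteration of `x = A^-1 y - u(x)` on the supplied
#' grid, so the result satisfies `t(t_inv(y)) = y` to sub-voxel accuracy.
#'
#' @param transform a [TransformChain-class].
#' @param grid a [BrainVolume-class] (or DisplacementField) defining the grid
#'   on which to tabulate the inverse field; defaults to the chain's own
#'   field grid mapped through the affine.
#' @param iter fixed-point iterations.
#' @return A [TransformChain-class].
#' @export
invertTransform <- function(transform, grid = NULL, iter = 20L) {
  Ai <- solve(transform@affine)
  if (is.null(transform@field)) return(TransformChain(Ai))
  fld <- transform@field
  if (is.null(grid)) {
    gaff <- transform@affine %*% fld@affine
    gdim <- dim(fld@field)[1:3]
  } else {
    gaff <- grid@affine
    gdim <- if (is(grid, "BrainVolume")) volDim(grid) else dim(grid@field)[1:3]
  }
  y <- worldGrid(BrainVolume(array(0, gdim), affine = gaff))
  w <- t(Ai[1:3, 1:3] %*% t(y) + Ai[1:3, 4])
  x <- w
  for (i in seq_len(iter)) x <- w - sampleField(fld, x)
  u2 <- array(t(transform@affine[1:3, 1:3] %*% t(x) + transform@affine[1:3, 4]) - y,
              c(gdim, 3L))
  TransformChain(Ai, field = new("DisplacementField", field = u2, affine = gaff))
}

#' Compose two transforms
#'
#' Returns the chain equivalent to applying `b` then `a`:
#' `compose(a, b)(x) = a(b(x))`. Affine-with-affine and affine-after-field
#' compositions are exact; when `a` carries a field the composite field is
#' tabulated numerically on `b`'s (or `a`'s) field grid.
#'
#' @param a,b [TransformChain-class] objects or 4x4 matrices.
#' @return A [TransformChain-class].
#' @export
composeTransforms <- function(a, b) {
  if (is.matrix(a)) a <- TransformChain(a)
  if (is.matrix(b)) b <- TransformChain(b)
  C <- a@affine %*% b@affine
  if (is.null(a@field) && is.null(b@field)) return(TransformChain(C))
  if (is.null(a@field)) {
    # a(b(x)) = A B (x + u_b(x)) exactly
    return(TransformChain(C, field = b@field))
  }
  ref <- if (!is.null(b@field)) b@field else a@field
  gdim <- dim(ref@field)[1:3]
  gaff <- ref@affine
  x <- worldGrid(BrainVolume(array(0, gdim), affine = gaff))
  y <- applyTransform(a, applyTransform(b, x))
  Ci <- solve(C)
  u <- t(Ci[1:3, 1:3] %*% t(y) + Ci[1:3, 4]) - x
  TransformChain(C, field = new("DisplacementField",
                                field = array(u, c(gdim, 3L)), affine = gaff))
}

#' Log-Euclidean mean of transforms
#'
#' Affine parts are averaged through the matrix logarithm (the bi-invariant
#' first-order mean used for template unbiasing); displacement fields are
#' averaged voxelwise, with chains lacking a field contributing zero.
#'
#' @param transforms list of [TransformChain-class] or 4x4 matrices.
#' @return A [TransformChain-class].
#' @export
meanTransform <- function(transforms) {
  transforms <- lapply(transforms, function(t)
    if (is.matrix(t)) TransformChain(t) else t)
  logs <- lapply(transforms, function(t) matLog(t@affine))
  A <- matExp(Reduce(`+`, logs) / length(logs))
  A[4, ] <- c(0, 0, 0, 1)
  fields <- Filter(Negate(is.null), lapply(transforms, function(t) t@field))
  fld <- NULL
  if (length(fields)) {
    ref <- fields[[1]]
    acc <- array(0, dim(ref@field))
    for (f in fields) {
      if (!all(dim(f@field) == dim(ref@field)))
        stop("field grids must match for averaging")
      acc <- acc + f@field
    }
    fld <- new("DisplacementField", field = acc / length(transforms),
               affine = ref@affine)
  }
  TransformChain(A, field = fld)
}

#' Reflect a volume about the mid-sagittal plane
#'
#' Reflection about the world plane x = 0. When the grid is symmetric about
#' that plane (voxel centres map onto voxel centres) the flip is an exact
#' index reversal; otherwise the volume is resampled through the reflection.
#'
#' @param v a [BrainVolume-class] in AC-PC space (x = 0 mid-sagittal).
#' @return The reflected [BrainVolume-class] on the same grid.
#' @export
flipLR <- function(v) {
  A <- v@affine
  d <- volDim(v)
  axisAligned <- all(abs(A[2:3, 1]) < 1e-9) && all(abs(A[1, 2:3]) < 1e-9)
  centred <- abs(A[1, 4] + A[1, 1] * (d[1] - 1) / 2) < 1e-6 * abs(A[1, 1])
  if (axisAligned && centred) {
    return(BrainVolume(v@data[d[1]:1, , , drop = FALSE], affine = A))
  }
  refl <- diag(c(-1, 1, 1, 1))
  resampleVolume(v, TransformChain(refl), target = v, order = 1L)
}
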
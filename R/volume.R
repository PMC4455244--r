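#' @useDynLib ovatlas, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Accessors for BrainVolume geometry
#'
#' `volData` returns the raw intensity array, `volAffine` the 4x4 index-to-
#' world matrix, `volDim` the grid shape, `voxelSize` the per-axis spacing in
#' mm and `voxelVolume` the volume of one voxel in mm^3.
#'
#' @param x a [BrainVolume-class].
#' @return See description.
#' @export
volData <- function(x) x@data

#' @rdname volData
#' @export
volAffine <- function(x) x@affine

#' @rdname volData
#' @export
volDim <- function(x) dim(x@data)

#' @rdname volData
#' @export
voxelSize <- function(x) sqrt(colSums(x@affine[1:3, 1:3]^2))

#' @rdname volData
#' @export
voxelVolume <- function(x) abs(det(x@affine[1:3, 1:3]))

setMethod("show", "BrainVolume", function(object) {
  d <- dim(object@data)
  sp <- signif(voxelSize(object), 4)
  cat(sprintf("BrainVolume: %d x %d x %d voxels, spacing %s mm\n",
              d[1], d[2], d[3], paste(sp, collapse = " x ")))
  cat(sprintf("  intensity range [%.3g, %.3g]\n",
              min(object@data), max(object@data)))
})

setMethod("show", "LandmarkSet", function(object) {
  cat("LandmarkSet with", nrow(object@coords), "points (mm):\n")
  print(round(object@coords, 2))
})

setMethod("show", "TransformChain", function(object) {
  cat("TransformChain\n  affine:\n")
  print(signif(object@affine, 6))
  if (is.null(object@field)) {
    cat("  field: none\n")
  } else {
    mag <- sqrt(rowSums(matrix(object@field@field, ncol = 3)^2))
    cat(sprintf("  field: %s grid, |u| mean %.3g mm, max %.3g mm\n",
                paste(dim(object@field@field)[1:3], collapse = "x"),
                mean(mag), max(mag)))
  }
})

setMethod("show", "StageResult", function(object) {
  cat(sprintf("StageResult [%s]: %d subjects, %d iterations\n",
              object@stage, length(object@transforms), object@iterations))
  cat(sprintf("  mean grid %s; in-grid mean SD %.3g\n",
              paste(volDim(object@meanVolume), collapse = "x"),
              mean(object@sdVolume@data)))
  if (length(object@excluded))
    cat("  excluded:", paste(object@excluded, collapse = ", "), "\n")
})

setMethod("show", "TissueProbabilityMaps", function(object) {
  cat(sprintf("TissueProbabilityMaps: %s grid from %d subjects\n",
              paste(volDim(object@gm), collapse = "x"), object@nSubjects))
})

setMethod("show", "SegmentationResult", function(object) {
  cat(sprintf("SegmentationResult: %d EM iterations, %sconverged\n",
              object@iterations, if (object@converged) "" else "NOT "))
  cat("  class means:", paste(sprintf("%s=%.2f", names(object@mu), object@mu),
                              collapse = ", "), "\n")
})

#' Coordinate helpers
#'
#' `indexToWorld` / `worldToIndex` convert between 0-based voxel indices and
#' world mm through a volume's affine. `worldGrid` returns the full n x 3
#' matrix of world coordinates of every voxel (column-major order).
#'
#' @param v a [BrainVolume-class] (or any object with an `affine` slot).
#' @param pts n x 3 matrix of points.
#' @return n x 3 matrix of converted points.
#' @keywords internal
indexToWorld <- function(v, pts) {
  A <- if (is.matrix(v)) v else v@affine
  t(A[1:3, 1:3] %*% t(pts) + A[1:3, 4])
}

#' @rdname indexToWorld
#' @keywords internal
worldToIndex <- function(v, pts) {
  A <- if (is.matrix(v)) v else v@affine
  Ai <- solve(A)
  t(Ai[1:3, 1:3] %*% t(pts) + Ai[1:3, 4])
}

#' @rdname indexToWorld
#' @keywords internal
worldGrid <- function(v) {
  d <- volDim(v)
  idx <- cbind(rep(seq_len(d[1]) - 1, times = d[2] * d[3]),
               rep(rep(seq_len(d[2]) - 1, each = d[1]), times = d[3]),
               rep(seq_len(d[3]) - 1, each = d[1] * d[2]))
  indexToWorld(v, idx)
}

#' Gaussian smoothing of a volume
#'
#' Separable Gaussian convolution with reflecting boundaries.
#'
#' @param v a [BrainVolume-class].
#' @param sigma_mm smoothing scale in mm (scalar or per-axis).
#' @return Smoothed [BrainVolume-class].
#' @export
smoothVolume <- function(v, sigma_mm) {
  sig_vox <- rep_len(sigma_mm, 3L) / voxelSize(v)
  d <- volDim(v)
  out <- cpp_gauss_smooth(as.numeric(v@data), as.integer(d), as.numeric(sig_vox))
  BrainVolume(array(out, d), affine = v@affine)
}

# block-average downsampling by an integer factor (with matching affine)
downsampleVolume <- function(v, factor) {
  if (factor == 1L) return(v)
  sm <- smoothVolume(v, voxelSize(v) * factor / 2)
  d <- volDim(v)
  nd <- pmax(floor((d - 1) / factor) + 1L, 2L)
  M <- rbind(diag(3) * factor, 0)
  M <- cbind(M, c(0, 0, 0, 1))
  idx <- cbind(rep(seq_len(nd[1]) - 1, times = nd[2] * nd[3]),
               rep(rep(seq_len(nd[2]) - 1, each = nd[1]), times = nd[3]),
               rep(seq_len(nd[3]) - 1, each = nd[1] * nd[2])) * factor
  vals <- cpp_sample(as.numeric(sm@data), as.integer(d),
                     idx + 0.0, 1L)
  aff <- v@affine %*% M
  BrainVolume(array(vals, nd), affine = aff)
}
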
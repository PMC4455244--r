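# Prior-weighted Gaussian-mixture EM tissue classification and volumetry.

#' Prior-based tissue segmentation (GMM-EM)
#'
#' Expectation-maximisation for a 4-class Gaussian mixture (CSF, GM, WM,
#' background) in which the voxelwise class priors are the tissue
#' probability maps (background prior = 1 - GM - WM - CSF). The E-step
#' posterior is proportional to prior x Gaussian likelihood; the M-step
#' re-estimates class means and variances from the posteriors. Class
#' parameters are initialised from prior-weighted moments (deterministic),
#' variances are floored at 1e-6 x intensity-range^2, and iteration stops
#' when the relative log-likelihood change falls below `tol`.
#'
#' @param v [BrainVolume-class], co-registered to the TPM grid.
#' @param tpm a [TissueProbabilityMaps-class] on the same grid, or a named
#'   list (gm, wm, csf) of probability volumes. Pass uniform maps to obtain
#'   an unsupervised mixture fit.
#' @param max_iter maximum EM iterations.
#' @param tol relative log-likelihood convergence tolerance.
#' @return A [SegmentationResult-class].
#' @export
segmentVolume <- function(v, tpm, max_iter = 100L, tol = 1e-6) {
  if (is(tpm, "TissueProbabilityMaps")) {
    pri <- list(csf = tpm@csf@data, gm = tpm@gm@data, wm = tpm@wm@data)
  } else {
    pri <- list(csf = tpm$csf@data, gm = tpm$gm@data, wm = tpm$wm@data)
  }
  d <- volDim(v)
  for (p in pri) if (!all(dim(p) == d)) stop("TPM grid mismatch")
  x <- as.numeric(v@data)
  n <- length(x)
  P <- cbind(csf = as.numeric(pri$csf), gm = as.numeric(pri$gm),
             wm = as.numeric(pri$wm))
  P <- cbind(P, bg = pmax(1 - rowSums(P), 0))
  # regularise so no class has an exactly zero prior everywhere it matters
  eps <- 1e-4
  P <- (P + eps) / (1 + 4 * eps)
  wsum <- colSums(P)
  if (any(wsum < 1e-8)) stop("empty effective prior for a class")
  mu <- colSums(P * x) / wsum
  sig2 <- colSums(P * (x - rep(mu, each = n))^2) / wsum
  floor2 <- 1e-6 * diff(range(x))^2
  sig2 <- pmax(sig2, floor2)
  # with uninformative (near-equal) priors the moment initialisation is
  # degenerate; break the symmetry with evenly spaced means in T1w order
  # (background lowest, then CSF < GM < WM)
  if (diff(range(mu)) < 1e-3 * diff(range(x))) {
    sp <- seq(min(x), max(x), length.out = 4L)
    mu <- c(csf = sp[2], gm = sp[3], wm = sp[4], bg = sp[1])
    sig2 <- rep((diff(range(x)) / 8)^2, 4L)
  }
  ll <- numeric(0)
  converged <- FALSE
  it <- 0L
  post <- NULL
  # global class mixing weights (learned) modulate the spatial priors, so
  # uninformative priors reduce the model to an unsupervised GMM
  w <- colMeans(P)
  for (it in seq_len(max_iter)) {
    Pw <- sweep(P, 2, w / colMeans(P), `*`)
    Pw <- Pw / rowSums(Pw)
    lik <- vapply(1:4, function(k)
      Pw[, k] * stats::dnorm(x, mu[k], sqrt(sig2[k])), numeric(n))
    tot <- rowSums(lik)
    tot[tot < 1e-300] <- 1e-300
    ll <- c(ll, sum(log(tot)))
    post <- lik / tot
    wsum <- colSums(post)
    mu <- colSums(post * x) / pmax(wsum, 1e-12)
    sig2 <- pmax(colSums(post * (x - rep(mu, each = n))^2) /
                   pmax(wsum, 1e-12), floor2)
    w <- pmax(wsum / n, 1e-8)
    if (it > 1L && abs(ll[it] - ll[it - 1L]) <
        tol * max(abs(ll[it - 1L]), 1)) {
      converged <- TRUE
      break
    }
  }
  mk <- function(k) BrainVolume(array(post[, k], d), affine = v@affine)
  new("SegmentationResult",
      posteriors = list(csf = mk(1), gm = mk(2), wm = mk(3), bg = mk(4)),
      mu = stats::setNames(as.numeric(mu), c("csf", "gm", "wm", "bg")),
      sigma2 = stats::setNames(as.numeric(sig2), c("csf", "gm", "wm", "bg")),
      logLik = ll, converged = converged, iterations = it)
}

#' Hard labels from a segmentation
#'
#' Argmax-posterior labelling (0 background, 1 CSF, 2 GM, 3 WM).
#'
#' @param seg a [SegmentationResult-class].
#' @return [BrainVolume-class] of integer labels.
#' @export
hardLabels <- function(seg) {
  d <- volDim(seg@posteriors$gm)
  M <- cbind(bg = as.numeric(seg@posteriors$bg@data),
             csf = as.numeric(seg@posteriors$csf@data),
             gm = as.numeric(seg@posteriors$gm@data),
             wm = as.numeric(seg@posteriors$wm@data))
  BrainVolume(array(max.col(M, ties.method = "first") - 1L, d),
              affine = seg@posteriors$gm@affine)
}

#' Absolute tissue volumes from a segmentation
#'
#' Per class, the sum of posterior probabilities times the voxel volume
#' (soft volumes); `hard = TRUE` counts argmax labels instead. Total brain
#' volume is the sum of GM and WM.
#'
#' @param seg a [SegmentationResult-class].
#' @param voxel_volume_mm3 voxel volume; defaults to the posterior grid's.
#' @param hard threshold at the argmax posterior instead of summing
#'   soft posteriors.
#' @return One-row `data.frame` with gm_mL, wm_mL, csf_mL, total_brain_mL.
#' @export
tissueVolumes <- function(seg, voxel_volume_mm3 = NULL, hard = FALSE) {
  if (is.null(voxel_volume_mm3))
    voxel_volume_mm3 <- voxelVolume(seg@posteriors$gm)
  if (hard) {
    labs <- hardLabels(seg)@data
    v <- c(gm = sum(labs == 2L), wm = sum(labs == 3L), csf = sum(labs == 1L))
  } else {
    v <- c(gm = sum(seg@posteriors$gm@data),
           wm = sum(seg@posteriors$wm@data),
           csf = sum(seg@posteriors$csf@data))
  }
  v <- v * voxel_volume_mm3 / 1000
  data.frame(gm_mL = v[["gm"]], wm_mL = v[["wm"]], csf_mL = v[["csf"]],
             total_brain_mL = v[["gm"]] + v[["wm"]])
}

#' Cohort homogeneity check by mean pairwise covariance
#'
#' Computes each subject's mean voxelwise correlation with every other
#' subject (over masks or posterior volumes on a common grid) and flags
#' subjects lying more than `nsd` SDs below the group mean. Outliers are
#' reported, never excluded.
#'
#' @param volumes list (>= 3) of [BrainVolume-class] on a common grid.
#' @param nsd flagging threshold in group SDs.
#' @return `data.frame` with subject, mean_correlation and flagged.
#' @export
homogeneityCheck <- function(volumes, nsd = 2) {
  if (length(volumes) < 3L) stop("need at least 3 subjects")
  ref <- volumes[[1]]
  X <- vapply(volumes, function(v) {
    if (!all(volDim(v) == volDim(ref))) stop("grid mismatch")
    as.numeric(v@data)
  }, numeric(prod(volDim(ref))))
  C <- stats::cor(X)
  meanCor <- (rowSums(C) - 1) / (ncol(C) - 1)
  thr <- mean(meanCor) - nsd * stats::sd(meanCor)
  ids <- names(volumes)
  if (is.null(ids)) ids <- sprintf("subj%03d", seq_along(volumes))
  data.frame(subject = ids, mean_correlation = meanCor,
             flagged = meanCor < thr, stringsAsFactors = FALSE,
             row.names = NULL)
}
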
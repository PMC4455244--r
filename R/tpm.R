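# Tissue probability maps: propagate per-subject binary masks through the
# stored template transforms and average.

#' Propagate a binary mask through a transform
#'
#' Resamples a binary {0,1} mask onto the target grid through the chain with
#' linear interpolation, so boundary voxels take fractional values and the
#' across-subject average is a smooth probability.
#'
#' @param mask binary [BrainVolume-class].
#' @param chain a [TransformChain-class] (template world to subject world).
#' @param target_grid target [BrainVolume-class] or `list(dim=, affine=)`.
#' @return [BrainVolume-class] with values in \[0, 1\].
#' @export
propagateMask <- function(mask, chain, target_grid) {
  vals <- unique(as.numeric(mask@data))
  if (!all(vals %in% c(0, 1))) stop("mask must be binary {0,1}")
  out <- resampleVolume(mask, chain, target = target_grid, order = 1L)
  out@data <- pmin(pmax(out@data, 0), 1)
  out
}

#' Average propagated masks into tissue probability maps
#'
#' Voxelwise mean per class of the propagated per-subject masks; with
#' mutually exclusive input masks the class probabilities sum to at most 1
#' at every voxel.
#'
#' @param gm,wm,csf lists of propagated [BrainVolume-class] masks, one per
#'   subject, equal lengths, common grid.
#' @return A [TissueProbabilityMaps-class].
#' @export
averageTpm <- function(gm, wm, csf) {
  n <- length(gm)
  if (length(wm) != n || length(csf) != n)
    stop("equal subject counts required per class")
  avg <- function(lst) {
    ref <- lst[[1]]
    for (v in lst)
      if (!all(volDim(v) == volDim(ref)) ||
          max(abs(v@affine - ref@affine)) > 1e-6)
        stop("grid mismatch between propagated masks")
    acc <- Reduce(`+`, lapply(lst, function(v) v@data)) / n
    BrainVolume(pmin(pmax(acc, 0), 1), affine = ref@affine)
  }
  g <- avg(gm); w <- avg(wm); cf <- avg(csf)
  # clip tiny interpolation overshoot of the class sum
  s <- g@data + w@data + cf@data
  over <- s > 1
  if (any(over)) {
    sc <- ifelse(over, 1 / s, 1)
    g@data <- g@data * sc; w@data <- w@data * sc; cf@data <- cf@data * sc
  }
  new("TissueProbabilityMaps", gm = g, wm = w, csf = cf,
      nSubjects = as.integer(n))
}

#' Binary class masks from a label volume
#'
#' @param labels [BrainVolume-class] of integer labels
#'   (0 background, 1 CSF, 2 GM, 3 WM).
#' @return Named list of binary [BrainVolume-class] masks (gm, wm, csf).
#' @export
masksFromLabels <- function(labels) {
  mk <- function(k) BrainVolume(array(as.numeric(labels@data == k),
                                      volDim(labels)), affine = labels@affine)
  list(gm = mk(2L), wm = mk(3L), csf = mk(1L))
}

#' Threshold-based tissue mask initialisation
#'
#' A simple class-interval thresholding of a normalised T1w-like volume:
#' voxels are assigned to CSF, GM or WM by nearest class mean, with
#' intensities below the background cut left unassigned. Mirrors a
#' threshold-plus-editing mask workflow as a fully automatic initialiser.
#'
#' @param v normalised [BrainVolume-class].
#' @param classMeans named intensities (csf, gm, wm).
#' @param background intensities below this are background.
#' @return Named list of binary masks (gm, wm, csf).
#' @export
thresholdMasks <- function(v, classMeans = c(csf = 25, gm = 55, wm = 75),
                           background = 12.5) {
  x <- v@data
  mu <- classMeans[c("csf", "gm", "wm")]
  cl <- apply(abs(outer(as.numeric(x), mu, `-`)), 1, which.min)
  cl[as.numeric(x) < background] <- 0L
  cl <- array(cl, volDim(v))
  mk <- function(k) BrainVolume(array(as.numeric(cl == k), volDim(v)),
                                affine = v@affine)
  list(gm = mk(2L), wm = mk(3L), csf = mk(1L))
}

#' Build TPMs from a subject population and stage transforms
#'
#' Convenience wrapper: converts each subject's label volume into binary
#' masks, propagates them through the subject's template transform, and
#' averages. The TPM grid defaults to 2x the template voxel size, mirroring
#' the template-to-TPM resolution relationship.
#'
#' @param labelVolumes named list of per-subject label [BrainVolume-class].
#' @param transforms named list of per-subject [TransformChain-class]
#'   (template world to subject world), e.g. from a [StageResult-class].
#' @param template the template [BrainVolume-class] defining the frame.
#' @param factor integer coarsening factor of the TPM grid.
#' @return A [TissueProbabilityMaps-class].
#' @export
buildTpm <- function(labelVolumes, transforms, template, factor = 2L) {
  ids <- intersect(names(labelVolumes), names(transforms))
  if (length(ids) < 1L) stop("no subjects shared between labels and transforms")
  grid <- downsampleVolume(template, as.integer(factor))
  prop <- lapply(ids, function(id) {
    masks <- masksFromLabels(labelVolumes[[id]])
    lapply(masks, propagateMask, chain = transforms[[id]], target_grid = grid)
  })
  averageTpm(gm = lapply(prop, `[[`, "gm"),
             wm = lapply(prop, `[[`, "wm"),
             csf = lapply(prop, `[[`, "csf"))
}
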
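#' @import methods
NULL

#' 3D scalar volume with world-coordinate geometry
#'
#' The universal image currency of the package: a 3D array of intensities
#' plus a 4x4 affine mapping 0-based voxel indices (i, j, k) to world
#' coordinates in millimetres. World axes follow the stereotaxic convention
#' +x right, +y rostral, +z dorsal.
#'
#' @slot data 3D numeric array of voxel intensities.
#' @slot affine 4x4 numeric matrix, 0-based index to world (mm).
#' @export
setClass("BrainVolume",
         representation(data = "array", affine = "matrix"))

setValidity("BrainVolume", function(object) {
  if (length(dim(object@data)) != 3L) return("data must be a 3D array")
  if (!all(dim(object@affine) == c(4L, 4L))) return("affine must be 4x4")
  if (abs(det(object@affine)) < 1e-12) return("affine must be invertible")
  if (!all(is.finite(object@affine))) return("affine must be finite")
  sp <- sqrt(colSums(object@affine[1:3, 1:3]^2))
  if (any(sp <= 0)) return("voxel spacing must be positive")
  TRUE
})

#' Construct a BrainVolume
#'
#' @param data 3D numeric array.
#' @param affine optional 4x4 index-to-world matrix. If omitted, an
#'   axis-aligned grid with the given spacing, centred on the world origin,
#'   is used (so the mid-sagittal plane x = 0 bisects the grid).
#' @param spacing isotropic or per-axis voxel size in mm (used only when
#'   `affine` is missing).
#' @return A [BrainVolume-class] object.
#' @export
BrainVolume <- function(data, affine = NULL, spacing = 1) {
  data <- as.array(data)
  if (is.null(affine)) {
    spacing <- rep_len(as.numeric(spacing), 3L)
    affine <- diag(c(spacing, 1))
    affine[1:3, 4] <- -spacing * (dim(data) - 1) / 2
  }
  new("BrainVolume", data = data, affine = affine)
}

#' Named anatomical landmark coordinates
#'
#' World-coordinate (mm) positions of named anatomical landmarks. The
#' canonical set used for rigid initialisation and AC-PC alignment is
#' AC, PC, eye_L, eye_R, pole_rostral, pole_caudal and cruciate.
#'
#' @slot coords numeric matrix, one row per landmark, columns x/y/z (mm);
#'   rownames carry the landmark names.
#' @export
setClass("LandmarkSet", representation(coords = "matrix"))

setValidity("LandmarkSet", function(object) {
  if (ncol(object@coords) != 3L) return("coords must have 3 columns")
  if (is.null(rownames(object@coords))) return("landmarks must be named")
  if (anyDuplicated(rownames(object@coords))) return("landmark names must be unique")
  if (!all(is.finite(object@coords))) return("landmark coordinates must be finite")
  nm <- rownames(object@coords)
  if (all(c("AC", "PC") %in% nm) &&
      sqrt(sum((object@coords["AC", ] - object@coords["PC", ])^2)) < 1e-9)
    return("AC and PC must be distinct")
  TRUE
})

#' @param coords numeric matrix with rownames, or a named list of length-3
#'   numeric vectors.
#' @rdname LandmarkSet-class
#' @export
LandmarkSet <- function(coords) {
  if (is.list(coords)) coords <- do.call(rbind, coords)
  colnames(coords) <- c("x", "y", "z")
  new("LandmarkSet", coords = coords)
}

#' Dense displacement field
#'
#' A vector field of world-space displacements (mm) sampled on its own grid.
#' Displacements are stored in world millimetres so composition with
#' affine transforms is grid-independent.
#'
#' @slot field 4D numeric array (nx, ny, nz, 3) of displacements in mm.
#' @slot affine 4x4 index-to-world matrix of the field grid.
#' @export
setClass("DisplacementField",
         representation(field = "array", affine = "matrix"))

setValidity("DisplacementField", function(object) {
  d <- dim(object@field)
  if (length(d) != 4L || d[4] != 3L) return("field must be (nx,ny,nz,3)")
  if (!all(is.finite(object@field))) return("field must be finite")
  if (!all(dim(object@affine) == c(4L, 4L))) return("affine must be 4x4")
  TRUE
})

#' Affine + optional non-linear transform
#'
#' Maps fixed-frame (template) world coordinates to moving-frame (subject)
#' world coordinates, the pull-back convention used for resampling:
#' `t(x) = A (x + u(x))` where `u` is the displacement field (evaluated in
#' the fixed frame) and `A` the affine part.
#'
#' @slot affine 4x4 world-to-world matrix.
#' @slot field a [DisplacementField-class] or `NULL`.
#' @export
setClass("TransformChain",
         representation(affine = "matrix", field = "ANY"))

setValidity("TransformChain", function(object) {
  if (!all(dim(object@affine) == c(4L, 4L))) return("affine must be 4x4")
  if (abs(det(object@affine)) < 1e-12) return("affine must be invertible")
  if (!is.null(object@field) && !is(object@field, "DisplacementField"))
    return("field must be NULL or a DisplacementField")
  TRUE
})

#' @param affine 4x4 world-to-world matrix (default identity).
#' @param field optional [DisplacementField-class].
#' @rdname TransformChain-class
#' @export
TransformChain <- function(affine = diag(4), field = NULL) {
  new("TransformChain", affine = affine, field = field)
}

#' Tissue probability maps
#'
#' Per-voxel prior probabilities for the GM, WM and CSF classes on a common
#' grid, obtained by averaging aligned binary tissue masks across subjects.
#'
#' @slot gm,wm,csf [BrainVolume-class] probability volumes in \[0, 1\].
#' @slot nSubjects number of subjects averaged.
#' @export
setClass("TissueProbabilityMaps",
         representation(gm = "BrainVolume", wm = "BrainVolume",
                        csf = "BrainVolume", nSubjects = "integer"))

setValidity("TissueProbabilityMaps", function(object) {
  dims <- list(dim(object@gm@data), dim(object@wm@data), dim(object@csf@data))
  if (!all(vapply(dims, function(d) all(d == dims[[1]]), logical(1))))
    return("class grids must be identical")
  if (max(abs(object@gm@affine - object@wm@affine),
          abs(object@gm@affine - object@csf@affine)) > 1e-6)
    return("class affines must be identical")
  vals <- c(object@gm@data, object@wm@data, object@csf@data)
  if (min(vals) < -1e-9 || max(vals) > 1 + 1e-9)
    return("probabilities must lie in [0, 1]")
  if (max(object@gm@data + object@wm@data + object@csf@data) > 1 + 1e-6)
    return("GM+WM+CSF must not exceed 1")
  TRUE
})

#' One stage of the iterative template average
#'
#' @slot meanVolume,sdVolume voxelwise mean and standard deviation across the
#'   resampled (and left-right augmented) subjects at the final iteration.
#' @slot transforms named list of per-subject [TransformChain-class]
#'   (unflipped subjects only), mapping template world to subject world.
#' @slot stage one of "rigid", "affine", "nonlinear".
#' @slot iterations number of template iterations run.
#' @slot trace list of per-iteration diagnostics (similarity summaries).
#' @slot excluded character vector of subjects dropped by registration failure.
#' @export
setClass("StageResult",
         representation(meanVolume = "BrainVolume", sdVolume = "BrainVolume",
                        transforms = "list", stage = "character",
                        iterations = "integer", trace = "list",
                        excluded = "character"))

setValidity("StageResult", function(object) {
  if (!object@stage %in% c("rigid", "affine", "nonlinear"))
    return("stage must be rigid/affine/nonlinear")
  if (min(object@sdVolume@data) < -1e-9) return("sd volume must be >= 0")
  if (!all(dim(object@meanVolume@data) == dim(object@sdVolume@data)))
    return("mean and sd grids must match")
  TRUE
})

#' Prior-based tissue segmentation result
#'
#' @slot posteriors named list (gm, wm, csf, bg) of [BrainVolume-class]
#'   posterior probability volumes.
#' @slot mu,sigma2 fitted class intensity means and variances.
#' @slot logLik per-iteration log-likelihood trace.
#' @slot converged logical.
#' @slot iterations EM iterations run.
#' @export
setClass("SegmentationResult",
         representation(posteriors = "list", mu = "numeric", sigma2 = "numeric",
                        logLik = "numeric", converged = "logical",
                        iterations = "integer"))

#' Phantom generation parameters
#'
#' Defines a synthetic T1w-like brain phantom: anatomy scale, class
#' intensities, inter-subject deformation statistics, bias-field amplitude
#' and noise level. Class intensities are on the 0-100 normalised scale and
#' must be T1w-ordered (CSF < GM < WM).
#'
#' @slot gridShape voxels per axis (>= 32).
#' @slot voxelSize isotropic voxel size, mm.
#' @slot classMeans named intensities for background, csf, gm, wm.
#' @slot deformAmplitude max smooth random displacement, mm.
#' @slot deformSmoothness Gaussian scale of the random field, mm.
#' @slot biasAmplitude multiplicative bias half-range (0.2 = +/-20 percent).
#' @slot noiseSd additive noise SD, intensity units.
#' @slot noiseModel "gaussian" or "rician".
#' @slot wmRadius normalised WM boundary radius (fraction of brain radius).
#' @slot gmRadius normalised outer GM boundary radius (WM < GM < 1; the
#'   remainder up to 1 is the exterior CSF rim).
#' @slot gyralAmplitude relative amplitude of the sinusoidal gyral undulation.
#' @slot brainAxes outer brain semi-axes, mm (shrunk automatically if the
#'   grid cannot contain them).
#' @slot ventricles logical; carve CSF ventricles into the WM core.
#' @slot seed RNG seed.
#' @export
setClass("PhantomSpec",
         representation(gridShape = "integer", voxelSize = "numeric",
                        classMeans = "numeric", deformAmplitude = "numeric",
                        deformSmoothness = "numeric", biasAmplitude = "numeric",
                        noiseSd = "numeric", noiseModel = "character",
                        wmRadius = "numeric", gmRadius = "numeric",
                        gyralAmplitude = "numeric",
                        brainAxes = "numeric", ventricles = "logical",
                        seed = "integer"))

setValidity("PhantomSpec", function(object) {
  if (length(object@gridShape) != 3L || any(object@gridShape < 32L))
    return("gridShape must be >= 32 per axis")
  if (object@voxelSize <= 0) return("voxelSize must be positive")
  cm <- object@classMeans
  if (!all(c("background", "csf", "gm", "wm") %in% names(cm)))
    return("classMeans must name background, csf, gm, wm")
  if (!(cm["csf"] < cm["gm"] && cm["gm"] < cm["wm"]))
    return("T1w ordering requires CSF < GM < WM")
  if (object@noiseSd < 0) return("noiseSd must be >= 0")
  if (!(object@wmRadius < object@gmRadius && object@gmRadius < 1))
    return("need wmRadius < gmRadius < 1")
  if (!object@noiseModel %in% c("gaussian", "rician"))
    return("noiseModel must be gaussian or rician")
  TRUE
})

#' @param gridShape,voxelSize,classMeans,deformAmplitude,deformSmoothness
#'   see slots.
#' @param biasAmplitude,noiseSd,noiseModel,wmRadius,gyralAmplitude see slots.
#' @param brainAxes,ventricles,seed see slots.
#' @rdname PhantomSpec-class
#' @export
phantomSpec <- function(gridShape = c(64L, 64L, 64L), voxelSize = 1,
                        classMeans = c(background = 0, csf = 25, gm = 55, wm = 75),
                        deformAmplitude = 3, deformSmoothness = 8,
                        biasAmplitude = 0.2, noiseSd = 5,
                        noiseModel = "gaussian", wmRadius = 0.62,
                        gmRadius = 0.85, gyralAmplitude = 0.08,
                        brainAxes = c(15, 20, 14),
                        ventricles = TRUE, seed = 1L) {
  new("PhantomSpec", gridShape = as.integer(rep_len(gridShape, 3L)),
      voxelSize = voxelSize, classMeans = classMeans,
      deformAmplitude = deformAmplitude, deformSmoothness = deformSmoothness,
      biasAmplitude = biasAmplitude, noiseSd = noiseSd,
      noiseModel = noiseModel, wmRadius = wmRadius, gmRadius = gmRadius,
      gyralAmplitude = gyralAmplitude,
      brainAxes = rep_len(as.numeric(brainAxes), 3L),
      ventricles = isTRUE(ventricles), seed = as.integer(seed))
}

#' Ground truth attached to a phantom
#'
#' @slot labels [BrainVolume-class] of integer class labels
#'   (0 background, 1 CSF, 2 GM, 3 WM).
#' @slot landmarks [LandmarkSet-class] in the phantom's world frame.
#' @slot trueTransform the [TransformChain-class] used to derive the subject
#'   from the base phantom (maps subject world to base world), or `NULL`.
#' @slot trueVolumes named per-class volumes (csf, gm, wm) in mL.
#' @export
setClass("GroundTruth",
         representation(labels = "BrainVolume", landmarks = "LandmarkSet",
                        trueTransform = "ANY", trueVolumes = "numeric"))

setValidity("GroundTruth", function(object) {
  labs <- unique(as.integer(object@labels@data))
  if (!all(labs %in% 0:3)) return("labels must be in {0,1,2,3}")
  TRUE
})

#' Synthetic cohort parameters
#'
#' Demographic and volumetric structure for simulated cohorts: body weight
#' and age are drawn from (zero-truncated) normals, GM carries a body-weight
#' effect and WM an age effect whose residual noise is calibrated so the
#' linear model's partial explained variance recovers the requested value
#' at the cohort's sample size (see the methods vignette).
#'
#' @slot nSubjects cohort size (>= 3).
#' @slot sexCounts named integer counts (male, female); must sum to nSubjects.
#' @slot bwMean,bwSd body weight distribution, kg.
#' @slot ageMean,ageSd age distribution, months.
#' @slot effectBwOnGm generating body-weight effect on GM, mL per kg.
#' @slot partialVarBwGm target partial explained variance of BW on GM
#'   (fraction in \[0, 1)).
#' @slot partialVarAgeWm target partial explained variance of age on WM.
#' @slot baseVolumes named cohort-mean volumes (gm, wm, csf), mL.
#' @slot wmSd,csfSd residual SDs for WM and CSF, mL.
#' @slot seed RNG seed.
#' @export
setClass("CohortSpec",
         representation(nSubjects = "integer", sexCounts = "integer",
                        bwMean = "numeric", bwSd = "numeric",
                        ageMean = "numeric", ageSd = "numeric",
                        effectBwOnGm = "numeric", partialVarBwGm = "numeric",
                        partialVarAgeWm = "numeric", baseVolumes = "numeric",
                        wmSd = "numeric", csfSd = "numeric", seed = "integer"))

setValidity("CohortSpec", function(object) {
  if (object@nSubjects < 3L) return("need at least 3 subjects")
  if (sum(object@sexCounts) != object@nSubjects)
    return("sexCounts must sum to nSubjects")
  if (object@bwSd <= 0 || object@ageSd <= 0) return("SDs must be positive")
  if (object@partialVarBwGm < 0 || object@partialVarBwGm >= 1 ||
      object@partialVarAgeWm < 0 || object@partialVarAgeWm >= 1)
    return("partial variances must lie in [0, 1)")
  if (!all(c("gm", "wm", "csf") %in% names(object@baseVolumes)))
    return("baseVolumes must name gm, wm, csf")
  TRUE
})

#' @param nSubjects,sexCounts,bwMean,bwSd,ageMean,ageSd see slots. Defaults
#'   mirror the 38-animal proof-of-principle cohort (26 neutered rams,
#'   12 ewes; BW 52.5 +/- 10.5 kg; age 12.9 +/- 4.5 months).
#' @param effectBwOnGm,partialVarBwGm,partialVarAgeWm generating effect
#'   structure (defaults: 0.20 mL/kg, 15.3 percent, 13.6 percent).
#' @param baseVolumes,wmSd,csfSd cohort-mean volumes and residual SDs (mL).
#' @param seed RNG seed.
#' @rdname CohortSpec-class
#' @export
cohortSpec <- function(nSubjects = 38L, sexCounts = c(male = 26L, female = 12L),
                       bwMean = 52.5, bwSd = 10.5, ageMean = 12.9, ageSd = 4.5,
                       effectBwOnGm = 0.20, partialVarBwGm = 0.153,
                       partialVarAgeWm = 0.136,
                       baseVolumes = c(gm = 51.5, wm = 35.6, csf = 29.7),
                       wmSd = 3.7, csfSd = 3.5, seed = 1L) {
  new("CohortSpec", nSubjects = as.integer(nSubjects),
      sexCounts = stats::setNames(as.integer(sexCounts), names(sexCounts)),
      bwMean = bwMean, bwSd = bwSd, ageMean = ageMean, ageSd = ageSd,
      effectBwOnGm = effectBwOnGm, partialVarBwGm = partialVarBwGm,
      partialVarAgeWm = partialVarAgeWm, baseVolumes = baseVolumes,
      wmSd = wmSd, csfSd = csfSd, seed = as.integer(seed))
}
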
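# End-to-end pipeline orchestration and configuration.

#' Pipeline configuration
#'
#' Collects the tunable constants of the full pipeline. Defaults follow the
#' template-building schedule (8 rigid and 8 affine iterations; demons at
#' 4, 2 and 1 mm with 4 iterations each), spline order 4 for scans and 1
#' for masks, and a TPM grid 2x coarser than the template grid.
#'
#' @param n_subjects phantom population size.
#' @param grid_shape,voxel_size phantom grid (voxels, mm).
#' @param n_iter_rigid,n_iter_affine linear template iterations.
#' @param schedule demons schedule, list of `c(step_mm, n_iter)` decreasing.
#' @param interp_order_scan,interp_order_mask interpolation orders.
#' @param tpm_factor TPM grid coarsening factor.
#' @param maxit optimiser cap per registration.
#' @param seed master seed.
#' @return A list of class `ovatlas_config`.
#' @export
pipelineConfig <- function(n_subjects = 8L, grid_shape = 48L, voxel_size = 1,
                           n_iter_rigid = 8L, n_iter_affine = 8L,
                           schedule = list(c(4, 4), c(2, 4), c(1, 4)),
                           interp_order_scan = 4L, interp_order_mask = 1L,
                           tpm_factor = 2L, maxit = c(300L, 200L, 120L), seed = 1L) {
  steps <- vapply(schedule, `[`, numeric(1), 1)
  if (any(diff(steps) >= 0)) stop("schedule steps must be strictly decreasing")
  if (n_iter_rigid < 1L || n_iter_affine < 1L) stop("iteration counts >= 1")
  if (voxel_size <= 0) stop("voxel size must be positive")
  structure(list(n_subjects = as.integer(n_subjects),
                 grid_shape = as.integer(grid_shape),
                 voxel_size = voxel_size,
                 n_iter_rigid = as.integer(n_iter_rigid),
                 n_iter_affine = as.integer(n_iter_affine),
                 schedule = schedule,
                 interp_order_scan = as.integer(interp_order_scan),
                 interp_order_mask = as.integer(interp_order_mask),
                 tpm_factor = as.integer(tpm_factor),
                 maxit = as.integer(maxit), seed = as.integer(seed)),
            class = "ovatlas_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match [pipelineConfig()] arguments.
#' @return A list of class `ovatlas_config`.
#' @export
readConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$schedule))
    vals$schedule <- lapply(vals$schedule, as.numeric)
  do.call(pipelineConfig, vals)
}

#' Run the full phantom-to-statistics pipeline
#'
#' Generates a phantom population, preprocesses every subject (bias
#' correction, 0-100 normalisation with histogram matching to the
#' reference, landmark rigid initialisation into the reference frame),
#' builds the three-stage template, computes QC, builds TPMs, segments each
#' subject with the TPM priors, tabulates tissue volumes and fits the
#' cohort model. Deterministic given the config seed.
#'
#' @param config an `ovatlas_config` (see [pipelineConfig()]).
#' @param out_dir optional directory; when given, artifacts (NIfTI volumes,
#'   transforms, QC CSV, cohort CSV, manifest JSON) are written there.
#' @return List with `template` (stage results), `qc`, `tpm`,
#'   `volumes` (per-subject tissue volumes), `cohort` (volumes + synthetic
#'   demographics), `fits` and `manifest`.
#' @export
runAll <- function(config = pipelineConfig(), out_dir = NULL) {
  spec <- phantomSpec(gridShape = config$grid_shape,
                      voxelSize = config$voxel_size, seed = config$seed)
  pop <- makePopulation(spec, config$n_subjects)
  ids <- names(pop$subjects)
  # preprocessing: bias correction then normalisation to the reference
  ref_id <- ids[1]
  pre <- lapply(pop$subjects, function(s) {
    mask <- s$volume@data > 0.25 * max(s$volume@data)
    bc <- correctBias(s$volume, mask)
    bc$corrected
  })
  refn <- normalizeIntensity(pre[[ref_id]])
  pre <- lapply(pre, normalizeIntensity, reference = refn)
  # landmark rigid initialisation into the reference AC-PC frame, so the
  # mid-sagittal plane sits at x = 0 as the symmetric averaging requires
  acpc <- acpcAlign(pop$subjects[[ref_id]]$truth@landmarks)
  acpc_inv <- solve(acpc)
  aligned <- lapply(ids, function(id) {
    lr <- landmarkRigid(pop$subjects[[ref_id]]$truth@landmarks,
                        pop$subjects[[id]]$truth@landmarks)
    resampleVolume(pre[[id]], TransformChain(lr$transform %*% acpc_inv),
                   target = pre[[ref_id]], order = config$interp_order_scan)
  })
  names(aligned) <- ids
  template <- runTemplatePipeline(aligned,
                                  n_iter_rigid = config$n_iter_rigid,
                                  n_iter_affine = config$n_iter_affine,
                                  schedule = config$schedule,
                                  maxit = config$maxit)
  # QC with ground-truth label masks of the reference frame (template-space
  # masks come from the final stage mean via thresholding)
  tmasks <- thresholdMasks(template$nonlinear@meanVolume)
  sampleQc <- do.call(rbind, lapply(ids, function(id) {
    m <- masksFromLabels(pop$subjects[[id]]$truth@labels)
    qcRecord(pop$subjects[[id]]$volume, m$gm@data > 0.5, m$wm@data > 0.5, id)
  }))
  templQc <- lapply(template, function(st)
    qcRecord(st@meanVolume, tmasks$gm@data > 0.5, tmasks$wm@data > 0.5,
             st@stage))
  qc <- qcCompare(sampleQc, templQc)
  # TPM from ground-truth labels propagated through the stage transforms
  labelVols <- lapply(pop$subjects, function(s) s$truth@labels)
  tpm <- buildTpm(labelVols, template$nonlinear@transforms,
                  template$nonlinear@meanVolume, factor = config$tpm_factor)
  # per-subject segmentation in the subject's rigidly aligned frame
  # (volume-preserving): the TPM priors are pulled back through the inverse
  # of the subject's template transform, mirroring prior-based segmentation
  # of co-registered native scans (retained subjects only)
  ids <- names(template$nonlinear@transforms)
  vols <- do.call(rbind, lapply(ids, function(id) {
    ch <- template$nonlinear@transforms[[id]]
    grid_sub <- aligned[[id]]
    inv <- invertTransform(ch, grid = grid_sub)
    pri <- lapply(list(gm = tpm@gm, wm = tpm@wm, csf = tpm@csf), function(p) {
      out <- resampleVolume(p, inv, target = grid_sub,
                            order = config$interp_order_mask)
      out@data <- pmin(pmax(out@data, 0), 1)
      out
    })
    seg <- segmentVolume(grid_sub, pri)
    cbind(subject_id = id, tissueVolumes(seg))
  }))
  # attach synthetic demographics and fit the cohort model
  cs <- cohortSpec(nSubjects = max(config$n_subjects, 6L),
                   sexCounts = c(male = ceiling(max(config$n_subjects, 6L) / 2),
                                 female = floor(max(config$n_subjects, 6L) / 2)),
                   seed = config$seed)
  demo <- makeCohort(cs)[seq_along(ids), ]
  cohort <- data.frame(subject_id = vols$subject_id, sex = demo$sex,
                       age_months = demo$age_months, bw_kg = demo$bw_kg,
                       gm_mL = vols$gm_mL, wm_mL = vols$wm_mL,
                       csf_mL = vols$csf_mL, stringsAsFactors = FALSE)
  cohort <- deriveMetrics(cohort)
  fits <- if (nrow(cohort) >= 5L && length(unique(cohort$sex)) > 1L)
    lapply(c("gm_mL", "wm_mL", "csf_mL"), function(dep)
      fitVolumeModel(cohort, dep))
  else NULL
  manifest <- list(seed = config$seed, n_subjects = config$n_subjects,
                   stages = lapply(template, function(st)
                     list(stage = st@stage, iterations = st@iterations,
                          excluded = st@excluded,
                          in_brain_mean_sd = stageSD(st))),
                   artifacts = character(0))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(mean_rig = "mean_rig.nii.gz", mean_affine = "mean_affine.nii.gz",
               mean_nl = "mean_nl.nii.gz")
    writeVolume(template$rigid@meanVolume, file.path(out_dir, paths[1]))
    writeVolume(template$affine@meanVolume, file.path(out_dir, paths[2]))
    writeVolume(template$nonlinear@meanVolume, file.path(out_dir, paths[3]))
    for (st in template)
      writeVolume(st@sdVolume,
                  file.path(out_dir, sprintf("sd_%s.nii.gz", st@stage)))
    writeVolume(tpm@gm, file.path(out_dir, "tpm_gm.nii.gz"))
    writeVolume(tpm@wm, file.path(out_dir, "tpm_wm.nii.gz"))
    writeVolume(tpm@csf, file.path(out_dir, "tpm_csf.nii.gz"))
    for (id in ids)
      writeAffine(template$nonlinear@transforms[[id]],
                  file.path(out_dir, sprintf("xfm_%s.txt", id)))
    writeCohort(cohort, file.path(out_dir, "cohort.csv"))
    files <- list.files(out_dir)
    manifest$artifacts <- stats::setNames(
      vapply(file.path(out_dir, files), function(f)
        unname(tools::md5sum(f)), character(1)), files)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(template = template, qc = qc, tpm = tpm, volumes = vols,
       cohort = cohort, fits = fits, manifest = manifest)
}
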
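# Iterative, left-right symmetric, unbiased population template averaging.

# fixed-point log-Euclidean unbiasing: returns the correction C such that
# the log-mean of {A_i %*% C} is the identity to tol
unbiasCorrection <- function(affines, tol = 1e-9, maxit = 50L) {
  C <- diag(4)
  for (it in seq_len(maxit)) {
    logs <- lapply(affines, function(A) matLog(A %*% C))
    M <- Reduce(`+`, logs) / length(logs)
    if (max(abs(M)) < tol) break
    C <- C %*% matExp(-M)
  }
  C
}

subjectVolumes <- function(volumes) {
  if (is.null(names(volumes)))
    names(volumes) <- sprintf("subj%03d", seq_along(volumes))
  volumes
}

#' One stage of symmetric unbiased template averaging
#'
#' Iterative loop: (i) the subject set is augmented with left-right flipped
#' copies; (ii) every volume (flipped and unflipped) is registered to the
#' current target (first iteration: the designated reference, a prior
#' stage's mean, or the stack average); (iii) the per-subject transforms are
#' unbiased by composing with the correction that makes the log-Euclidean
#' mean of the unflipped transforms the identity (for the non-linear stage,
#' the mean displacement field is subtracted); (iv) all volumes are
#' resampled through their transforms and averaged into the new target.
#' After the final iteration the voxelwise SD across the resampled volumes
#' (flipped copies included) is computed.
#'
#' Subjects whose registration fails are excluded from that iteration's
#' average and recorded; fewer than 2 usable subjects is an error.
#'
#' @param volumes named list of preprocessed [BrainVolume-class] subjects on
#'   a common world frame.
#' @param stage "rigid", "affine" or "nonlinear".
#' @param n_iter template iterations (defaults: 8 for linear stages, 1 for
#'   the non-linear stage).
#' @param schedule demons schedule for the non-linear stage
#'   (see [registerNonlinear()]).
#' @param prior optional [StageResult-class] of the previous stage; its mean
#'   becomes the initial target and its transforms initialise this stage's.
#' @param reference name or index of the subject used as the first target
#'   when no prior is given.
#' @param maxit optimiser iteration cap(s) passed to [registerLinear()].
#' @return A [StageResult-class].
#' @export
buildStage <- function(volumes, stage = c("rigid", "affine", "nonlinear"),
                       n_iter = NULL, schedule = list(c(4, 4), c(2, 4), c(1, 4)),
                       prior = NULL, reference = 1L, maxit = c(300L, 200L, 120L)) {
  stage <- match.arg(stage)
  volumes <- subjectVolumes(volumes)
  if (length(volumes) < 2L) stop("need at least 2 volumes")
  if (is.null(n_iter)) n_iter <- if (stage == "nonlinear") 1L else 8L
  ids <- names(volumes)
  flipped <- lapply(volumes, flipLR)
  target <- if (!is.null(prior)) prior@meanVolume else volumes[[reference]]
  grid <- list(dim = volDim(target), affine = target@affine)
  inits <- if (!is.null(prior)) {
    lapply(prior@transforms, function(t) t@affine)
  } else {
    stats::setNames(rep(list(diag(4)), length(volumes)), ids)
  }
  initsF <- lapply(inits, function(A) diag(c(-1, 1, 1, 1)) %*% A %*% diag(c(-1, 1, 1, 1)))
  transforms <- NULL
  trace <- list()
  excluded <- character(0)
  resampled <- NULL
  for (it in seq_len(n_iter)) {
    chains <- vector("list", length(volumes))
    chainsF <- vector("list", length(volumes))
    ok <- rep(TRUE, length(volumes))
    sims <- rep(NA_real_, length(volumes))
    for (i in seq_along(volumes)) {
      res <- try({
        if (stage == "nonlinear") {
          A <- inits[[i]]
          warped <- resampleVolume(volumes[[i]], TransformChain(A),
                                   target = target, order = 1L)
          nl <- registerNonlinear(warped, target, schedule = schedule)
          chains[[i]] <- TransformChain(A, field = nl$field)
          AF <- initsF[[i]]
          warpedF <- resampleVolume(flipped[[i]], TransformChain(AF),
                                    target = target, order = 1L)
          nlF <- registerNonlinear(warpedF, target, schedule = schedule)
          chainsF[[i]] <- TransformChain(AF, field = nlF$field)
          sims[i] <- -nl$ssd_trace[[length(nl$ssd_trace)]]$ssd_after
        } else {
          dof <- if (stage == "rigid") 6L else 12L
          r <- registerLinear(volumes[[i]], target, dof = dof,
                              init = inits[[i]], maxit = maxit)
          rF <- registerLinear(flipped[[i]], target, dof = dof,
                               init = initsF[[i]], maxit = maxit)
          chains[[i]] <- TransformChain(r$transform)
          chainsF[[i]] <- TransformChain(rF$transform)
          sims[i] <- r$similarity
        }
        TRUE
      }, silent = TRUE)
      if (inherits(res, "try-error")) {
        ok[i] <- FALSE
        excluded <- union(excluded, ids[i])
      }
    }
    if (sum(ok) < 2L) stop("fewer than 2 usable subjects")
    Fm <- diag(c(-1, 1, 1, 1))
    # symmetrise: each subject's transform is averaged with the mirror
    # conjugate of its flipped copy's transform (both registrations
    # contribute), and the flipped copy takes the exact conjugate, making
    # the template left-right symmetric by construction
    mirrorField <- function(u) {
      uF <- u[dim(u)[1]:1, , , , drop = FALSE]
      uF[, , , 1] <- -uF[, , , 1]
      uF
    }
    for (i in which(ok)) {
      Async <- matExp((matLog(chains[[i]]@affine) +
                         matLog(Fm %*% chainsF[[i]]@affine %*% Fm)) / 2)
      Async[4, ] <- c(0, 0, 0, 1)
      chains[[i]]@affine <- Async
      chainsF[[i]]@affine <- Fm %*% Async %*% Fm
      if (!is.null(chains[[i]]@field)) {
        usym <- (chains[[i]]@field@field +
                   mirrorField(chainsF[[i]]@field@field)) / 2
        chains[[i]]@field@field <- usym
        chainsF[[i]]@field@field <- mirrorField(usym)
      }
    }
    # unbias: log-mean of the unflipped transforms becomes the identity;
    # flipped copies receive the mirror-conjugated correction so the
    # left-right pairing is preserved
    C <- unbiasCorrection(lapply(chains[ok], function(ch) ch@affine))
    CF <- Fm %*% C %*% Fm
    for (i in which(ok)) {
      chains[[i]]@affine <- chains[[i]]@affine %*% C
      chainsF[[i]]@affine <- chainsF[[i]]@affine %*% CF
    }
    if (stage == "nonlinear") {
      fields <- lapply(chains[ok], function(ch) ch@field@field)
      ubar <- Reduce(`+`, fields) / length(fields)
      # mirror of the mean field: reverse the x axis, negate the x component
      nx <- dim(ubar)[1]
      ubarF <- ubar[nx:1, , , , drop = FALSE]
      ubarF[, , , 1] <- -ubarF[, , , 1]
      for (i in which(ok)) {
        chains[[i]]@field@field <- chains[[i]]@field@field - ubar
        chainsF[[i]]@field@field <- chainsF[[i]]@field@field - ubarF
      }
    }
    resampled <- c(
      lapply(which(ok), function(i)
        resampleVolume(volumes[[i]], chains[[i]], target = grid, order = 1L)),
      lapply(which(ok), function(i)
        resampleVolume(flipped[[i]], chainsF[[i]], target = grid, order = 1L)))
    stack <- vapply(resampled, function(v) as.numeric(v@data),
                    numeric(prod(grid$dim)))
    target <- BrainVolume(array(rowMeans(stack), grid$dim), affine = grid$affine)
    trace[[it]] <- list(iteration = it, mean_similarity = mean(sims[ok]),
                        n_used = sum(ok))
    transforms <- stats::setNames(chains, ids)
    for (i in which(ok)) {
      inits[[i]] <- chains[[i]]@affine
      initsF[[i]] <- chainsF[[i]]@affine
    }
  }
  stack <- vapply(resampled, function(v) as.numeric(v@data),
                  numeric(prod(grid$dim)))
  sdvol <- apply(stack, 1, stats::sd)
  new("StageResult",
      meanVolume = target,
      sdVolume = BrainVolume(array(sdvol, grid$dim), affine = grid$affine),
      transforms = transforms[!ids %in% excluded],
      stage = stage, iterations = as.integer(n_iter),
      trace = trace, excluded = excluded)
}

#' Run the three-stage template pipeline
#'
#' Rigid, then full-affine, then non-linear symmetric unbiased averaging,
#' chaining each stage's transforms into the next as initialisation, in the
#' template-building convention of population-average atlases.
#'
#' @param volumes named list of preprocessed [BrainVolume-class] subjects.
#' @param n_iter_rigid,n_iter_affine linear-stage iteration counts
#'   (default 8 each).
#' @param schedule demons schedule (default 4 iterations each at
#'   4, 2 and 1 mm).
#' @param reference subject used as the first rigid target.
#' @param maxit optimiser cap per registration.
#' @return List with elements `rigid`, `affine`, `nonlinear`
#'   ([StageResult-class] each).
#' @export
runTemplatePipeline <- function(volumes, n_iter_rigid = 8L, n_iter_affine = 8L,
                                schedule = list(c(4, 4), c(2, 4), c(1, 4)),
                                reference = 1L, maxit = c(300L, 200L, 120L)) {
  rigid <- buildStage(volumes, "rigid", n_iter = n_iter_rigid,
                      reference = reference, maxit = maxit)
  affine <- buildStage(volumes, "affine", n_iter = n_iter_affine,
                       prior = rigid, maxit = maxit)
  nonlinear <- buildStage(volumes, "nonlinear", n_iter = 1L,
                          schedule = schedule, prior = affine)
  list(rigid = rigid, affine = affine, nonlinear = nonlinear)
}

#' Mean in-brain voxelwise SD of a stage
#'
#' Summarises a stage's SD map over the brain (template intensity above
#' `threshold`), the figure-of-merit that should decrease from the rigid to
#' the affine to the non-linear stage.
#'
#' @param stageResult a [StageResult-class].
#' @param threshold intensity defining "in-brain" on the stage mean.
#' @return Mean SD (intensity units) over in-brain voxels.
#' @export
stageSD <- function(stageResult, threshold = 10) {
  mask <- stageResult@meanVolume@data > threshold
  mean(stageResult@sdVolume@data[mask])
}
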
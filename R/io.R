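# NIfTI-1, landmark JSON, transform text and cohort CSV I/O.

#' Read / write volumes as NIfTI-1
#'
#' Volumes are stored as NIfTI-1 (optionally gzipped) with float32 data and
#' the index-to-world affine in the sform; the round trip preserves data and
#' geometry. 4D files are read back as displacement fields when they carry
#' 3 components.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `readVolume` returns a [BrainVolume-class] (or a
#'   [DisplacementField-class] for 3-component 4D files).
#' @export
readVolume <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- structure(RNifti::xform(img), class = "matrix")
  dimn <- dim(img)
  if (length(dimn) == 3L)
    return(BrainVolume(array(as.numeric(img), dimn), affine = unclass(aff)))
  if (length(dimn) == 4L && dimn[4] == 3L)
    return(new("DisplacementField", field = array(as.numeric(img), dimn),
               affine = unclass(aff)))
  stop("expected a 3D scalar volume or a 3-component 4D field")
}

#' @param v a [BrainVolume-class] or [DisplacementField-class].
#' @param datatype NIfTI storage type (default float32; use "int16" for
#'   label volumes if desired).
#' @rdname readVolume
#' @export
writeVolume <- function(v, path, datatype = "float") {
  arr <- if (is(v, "DisplacementField")) v@field else v@data
  aff <- if (is(v, "DisplacementField")) v@affine else v@affine
  img <- RNifti::asNifti(arr)
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  img <- RNifti::`qform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Read / write landmark sets as JSON
#'
#' Landmarks are stored as a JSON object mapping names to `[x, y, z]` world
#' coordinates in mm.
#'
#' @param path file path.
#' @return `readLandmarks` returns a [LandmarkSet-class].
#' @export
readLandmarks <- function(path) {
  lst <- jsonlite::read_json(path, simplifyVector = TRUE)
  LandmarkSet(lapply(lst, as.numeric))
}

#' @param lm a [LandmarkSet-class].
#' @rdname readLandmarks
#' @export
writeLandmarks <- function(lm, path) {
  lst <- stats::setNames(lapply(seq_len(nrow(lm@coords)),
                                function(i) as.numeric(lm@coords[i, ])),
                         rownames(lm@coords))
  jsonlite::write_json(lst, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' Read / write affine transforms as 4x4 text matrices
#'
#' Row-major whitespace-separated 4x4 world-coordinate (mm) matrices.
#'
#' @param path file path.
#' @return `readAffine` returns a 4x4 matrix.
#' @export
readAffine <- function(path) {
  m <- as.matrix(utils::read.table(path))
  dimnames(m) <- NULL
  if (!all(dim(m) == c(4L, 4L))) stop("expected a 4x4 matrix")
  m
}

#' @param a 4x4 matrix or affine-only [TransformChain-class].
#' @rdname readAffine
#' @export
writeAffine <- function(a, path) {
  if (is(a, "TransformChain")) a <- a@affine
  utils::write.table(format(a, digits = 17), path, quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write cohort tables as CSV
#'
#' Header: `subject_id,sex,age_months,bw_kg,gm_mL,wm_mL,csf_mL` (derived
#' columns, when present, are appended after these).
#'
#' @param path file path.
#' @return `readCohort` returns a `data.frame`.
#' @export
readCohort <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @param t cohort `data.frame`.
#' @rdname readCohort
#' @export
writeCohort <- function(t, path) {
  utils::write.csv(t, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
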
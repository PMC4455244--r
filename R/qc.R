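# Tissue-ROI image quality statistics: SNR, CNR and stage comparisons.

roiValues <- function(v, roi) {
  vals <- v@data[as.logical(roi)]
  if (!length(vals)) stop("ROI is empty")
  if (!all(is.finite(vals))) stop("non-finite intensities in ROI")
  vals
}

#' Signal-to-noise ratio over a tissue ROI
#'
#' The mean in-ROI gray value divided by the within-ROI standard deviation
#' (sample, n-1 normalisation), the ROI being a complete tissue class; the
#' value measures the homogeneity of gray values within the class.
#'
#' @param v a [BrainVolume-class].
#' @param roi_mask logical/0-1 array selecting the ROI.
#' @return Dimensionless SNR.
#' @export
snr <- function(v, roi_mask) {
  vals <- roiValues(v, roi_mask)
  s <- stats::sd(vals)
  if (s == 0) stop("ROI has zero variance; SNR undefined")
  mean(vals) / s
}

#' Contrast-to-noise ratio between WM and GM
#'
#' `(mean WM - mean GM) / sqrt((var WM + var GM) / 2)` with sample
#' variances: the WM-GM gray-value difference in units of the pooled
#' within-class standard deviation.
#'
#' @param v a [BrainVolume-class].
#' @param gm_mask,wm_mask disjoint ROI masks for the two classes.
#' @return Dimensionless CNR (positive when WM is brighter than GM).
#' @export
cnr <- function(v, gm_mask, wm_mask) {
  if (any(as.logical(gm_mask) & as.logical(wm_mask)))
    stop("GM and WM masks must be disjoint")
  g <- roiValues(v, gm_mask)
  w <- roiValues(v, wm_mask)
  pooled <- (stats::var(w) + stats::var(g)) / 2
  if (pooled == 0) stop("both ROIs have zero variance; CNR undefined")
  (mean(w) - mean(g)) / sqrt(pooled)
}

#' QC record for one image
#'
#' Computes SNR for GM and WM plus the GM/WM CNR of one image with the
#' given masks.
#'
#' @param v a [BrainVolume-class].
#' @param gm_mask,wm_mask tissue masks.
#' @param image_id identifier carried into the record.
#' @return One-row `data.frame` (image_id, snr_gm, snr_wm, cnr, n_gm, n_wm).
#' @export
qcRecord <- function(v, gm_mask, wm_mask, image_id = "image") {
  data.frame(image_id = image_id,
             snr_gm = snr(v, gm_mask), snr_wm = snr(v, wm_mask),
             cnr = cnr(v, gm_mask, wm_mask),
             n_gm = sum(as.logical(gm_mask)), n_wm = sum(as.logical(wm_mask)),
             stringsAsFactors = FALSE)
}

#' Compare per-subject quality against template values
#'
#' One-sample two-sided t-tests of the per-subject SNR/CNR distributions
#' against each template stage's scalar value, reporting means, confidence
#' intervals, p-values and the stage ordering.
#'
#' @param sample_records `data.frame` of [qcRecord()] rows (>= 3 subjects).
#' @param template_records named list (by stage) of one-row [qcRecord()]
#'   `data.frame`s for the stage templates.
#' @return `data.frame` with one row per stage x metric: the sample mean and
#'   95 percent CI, the template value, and the t-test p-value.
#' @export
qcCompare <- function(sample_records, template_records) {
  if (nrow(sample_records) < 3L) stop("need at least 3 sample records")
  metrics <- c("snr_gm", "snr_wm", "cnr")
  out <- do.call(rbind, lapply(names(template_records), function(stg) {
    do.call(rbind, lapply(metrics, function(m) {
      x <- sample_records[[m]]
      tv <- template_records[[stg]][[m]]
      tt <- stats::t.test(x, mu = tv)
      data.frame(stage = stg, metric = m,
                 sample_mean = mean(x), ci_lo = tt$conf.int[1],
                 ci_hi = tt$conf.int[2], template_value = tv,
                 p_value = tt$p.value, stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}
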
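# Cohort volumetrics: derived metrics, the sex+age+bodyweight linear model
# with partial explained variance, covariate adjustment and group tests.

#' Add derived volumetric metrics to a cohort table
#'
#' Appends per-subject total brain volume (GM + WM), the GM:WM, GM:total and
#' CSF:total ratios, and per-kg relative volumes (tissue / body weight) for
#' GM, WM, CSF and total brain.
#'
#' @param t cohort `data.frame` with columns `bw_kg, gm_mL, wm_mL, csf_mL`.
#' @return The table with columns `total_mL, gm_wm_ratio, gm_total_ratio,
#'   csf_total_ratio, gm_perkg, wm_perkg, csf_perkg, total_perkg` appended.
#' @export
deriveMetrics <- function(t) {
  need <- c("bw_kg", "gm_mL", "wm_mL", "csf_mL")
  if (!all(need %in% names(t))) stop("missing volume/bodyweight columns")
  if (any(t$wm_mL <= 0)) stop("zero or negative WM volume")
  if (any(t$bw_kg <= 0)) stop("non-positive body weight")
  t$total_mL <- t$gm_mL + t$wm_mL
  if (any(t$total_mL <= 0)) stop("zero total brain volume")
  t$gm_wm_ratio <- t$gm_mL / t$wm_mL
  t$gm_total_ratio <- t$gm_mL / t$total_mL
  t$csf_total_ratio <- t$csf_mL / t$total_mL
  t$gm_perkg <- t$gm_mL / t$bw_kg
  t$wm_perkg <- t$wm_mL / t$bw_kg
  t$csf_perkg <- t$csf_mL / t$bw_kg
  t$total_perkg <- t$total_mL / t$bw_kg
  t
}

#' Fit the cohort volume model with partial explained variance
#'
#' Ordinary least squares of `volume ~ age + bw + sex` (sex coded male = 0,
#' female = 1) with two-sided coefficient p-values. The variance explained
#' by each covariate is the squared partial correlation given the others,
#' in percent: `100 * t^2 / (t^2 + df)`, cross-checked against the
#' R-squared increment ratio.
#'
#' @param t cohort `data.frame` with `sex, age_months, bw_kg` and the
#'   dependent column.
#' @param dependent name of the volume column (e.g. `"gm_mL"`).
#' @return List of class `ovatlas_fit`: `dependent`, `n`, `residual_sd`,
#'   `fit` (the `lm` object) and `coefficients` (a `data.frame` with
#'   estimate, p_value and partial_explained_variance_pct per covariate).
#' @export
fitVolumeModel <- function(t, dependent) {
  if (nrow(t) < 5L) stop("need at least 5 subjects")
  if (length(unique(t$sex)) < 2L) stop("both sexes required")
  dat <- data.frame(y = t[[dependent]], age = t$age_months, bw = t$bw_kg,
                    sex = as.numeric(t$sex == "female"))
  fit <- stats::lm(y ~ age + bw + sex, data = dat)
  sf <- summary(fit)$coefficients
  qr_rank <- fit$rank
  if (qr_rank < 4L) stop("collinear design")
  df <- fit$df.residual
  terms <- c("age", "bw", "sex")
  pv <- vapply(terms, function(tm) {
    tval <- sf[tm, "t value"]
    100 * tval^2 / (tval^2 + df)
  }, numeric(1))
  # cross-check: R^2 increment ratio (squared partial correlation identity);
  # numerically undefined for an exact fit, where both routes saturate
  ssr_full <- sum(stats::residuals(fit)^2)
  ssy <- sum((dat$y - mean(dat$y))^2)
  if (ssr_full > 1e-10 * ssy) {
    pv2 <- vapply(terms, function(tm) {
      red <- stats::lm(stats::reformulate(setdiff(terms, tm), "y"), data = dat)
      ssr_red <- sum(stats::residuals(red)^2)
      100 * (ssr_red - ssr_full) / ssr_red
    }, numeric(1))
    if (max(abs(pv - pv2)) > 1e-8 * max(1, pv))
      stop("internal error: partial-variance identities disagree")
  }
  co <- data.frame(term = terms,
                   estimate = sf[terms, "Estimate"],
                   p_value = sf[terms, "Pr(>|t|)"],
                   partial_explained_variance_pct = pv,
                   row.names = NULL, stringsAsFactors = FALSE)
  structure(list(dependent = dependent, n = nrow(t),
                 residual_sd = sqrt(ssr_full / df),
                 coefficients = co, fit = fit),
            class = "ovatlas_fit")
}

#' @export
print.ovatlas_fit <- function(x, ...) {
  cat(sprintf("Volume model: %s ~ age + bw + sex (n = %d)\n",
              x$dependent, x$n))
  print(transform(x$coefficients,
                  estimate = signif(estimate, 4),
                  p_value = signif(p_value, 3),
                  partial_explained_variance_pct =
                    round(partial_explained_variance_pct, 1)))
  invisible(x)
}

#' Covariate-adjusted volumes
#'
#' Removes the fitted body-weight and age effects about their cohort means:
#' `y_adj = y - b_bw (bw - mean bw) - b_age (age - mean age)`. The adjusted
#' mean equals the raw mean exactly (centering identity).
#'
#' @param t cohort `data.frame`.
#' @param fit an `ovatlas_fit` for a dependent column of `t`.
#' @return The table with a `<dependent>_adj` column appended.
#' @export
adjustVolumes <- function(t, fit) {
  co <- fit$coefficients
  if (!all(c("bw", "age") %in% co$term)) stop("fit must include bw and age terms")
  b_bw <- co$estimate[co$term == "bw"]
  b_age <- co$estimate[co$term == "age"]
  y <- t[[fit$dependent]]
  adj <- y - b_bw * (t$bw_kg - mean(t$bw_kg)) -
    b_age * (t$age_months - mean(t$age_months))
  t[[paste0(fit$dependent, "_adj")]] <- adj
  t
}

#' Welch two-sample comparison by sex
#'
#' @param t cohort `data.frame`.
#' @param metric column to compare.
#' @param by grouping column (default `"sex"`).
#' @return List with group means, 95 percent CI of the difference and the
#'   two-sided Welch p-value.
#' @export
groupCompare <- function(t, metric, by = "sex") {
  g <- split(t[[metric]], t[[by]])
  if (length(g) != 2L || any(lengths(g) < 3L))
    stop("need two groups with at least 3 subjects each")
  tt <- stats::t.test(g[[1]], g[[2]])
  list(metric = metric, groups = names(g),
       means = vapply(g, mean, numeric(1)),
       sds = vapply(g, stats::sd, numeric(1)),
       conf_int = tt$conf.int, p_value = tt$p.value)
}

#' Normality checks for a cohort metric
#'
#' Kolmogorov-Smirnov test against the fitted normal and the Shapiro-Wilk
#' test.
#'
#' @param t cohort `data.frame`.
#' @param metric column to test.
#' @return List with `ks_p` and `shapiro_p`.
#' @export
normalityCheck <- function(t, metric) {
  x <- t[[metric]]
  if (length(x) < 3L || stats::sd(x) == 0) stop("degenerate sample")
  ks <- suppressWarnings(stats::ks.test(x, "pnorm", mean(x), stats::sd(x)))
  sw <- stats::shapiro.test(x)
  list(metric = metric, ks_p = ks$p.value, shapiro_p = sw$p.value)
}
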
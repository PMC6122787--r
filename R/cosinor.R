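#' Amplitude and acrophase from quadrature coefficients
#'
#' Converts the cosine/sine regression coefficients of a single-component
#' cosinor model into the rhythm's amplitude and acrophase.  The fitted
#' seasonal component \eqn{\beta_c \cos\theta + \beta_s \sin\theta} equals
#' \eqn{A \cos(\theta - \phi)} with \eqn{A = \sqrt{\beta_c^2 + \beta_s^2}}
#' and \eqn{\phi = \mathrm{atan2}(\beta_s, \beta_c)}.
#'
#' @param beta_cos,beta_sin numeric coefficient(s) on the cosine and sine
#'   regressors.
#' @return list with `amplitude` (>= 0) and `acrophase_rad` in `[0, 2*pi)`;
#'   the degenerate (0, 0) case returns acrophase 0 by convention.
#' @export
amplitude_acrophase <- function(beta_cos, beta_sin) {
  amplitude <- sqrt(beta_cos^2 + beta_sin^2)
  acro <- ifelse(amplitude == 0, 0, atan2(beta_sin, beta_cos) %% (2 * pi))
  list(amplitude = amplitude, acrophase_rad = acro)
}

#' Standardize an amplitude by a reference standard deviation
#'
#' Expresses a rhythm amplitude in SD units of the outcome, dividing by the
#' outcome's standard deviation in a reference sample (conventionally the
#' analysis sample at baseline).
#'
#' @param amplitude amplitude in outcome units (>= 0).
#' @param sd_ref reference standard deviation, must be > 0.
#' @return amplitude in SD units.
#' @export
standardized_amplitude <- function(amplitude, sd_ref) {
  if (!is.numeric(sd_ref) || any(!is.finite(sd_ref)) || any(sd_ref <= 0))
    stop("standardized_amplitude: sd_ref must be a positive number")
  amplitude / sd_ref
}

## Build the cosinor design pieces from a table.  Returns complete-case data
## with .cos/.sin columns, the covariate term labels, and a dropped-row count.
.cosinor_frame <- function(data, outcome, covariates, date_col, period_days,
                           cohort_col = NULL, extra_cols = character()) {
  stopifnot(is.data.frame(data))
  need <- unique(c(outcome, date_col, covariates, cohort_col, extra_cols))
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols))
    stop("column(s) not found: ", paste(missing_cols, collapse = ", "))
  keep <- stats::complete.cases(data[need])
  n_dropped <- sum(!keep)
  d <- data[keep, , drop = FALSE]
  if (!nrow(d)) stop("no complete rows for outcome '", outcome, "'")
  theta <- date_to_angle(d[[date_col]], period_days)
  d$.cos <- cos(theta)
  d$.sin <- sin(theta)
  terms <- covariates
  if (!is.null(cohort_col)) {
    d[[cohort_col]] <- factor(d[[cohort_col]])
    if (nlevels(d[[cohort_col]]) > 1L) terms <- c(terms, cohort_col)
  }
  list(data = d, theta = theta, terms = terms, n_dropped = n_dropped)
}

.check_full_rank <- function(fit) {
  co <- stats::coef(fit)
  if (anyNA(co))
    stop("rank-deficient design; collinear column(s): ",
         paste(names(co)[is.na(co)], collapse = ", "))
  invisible(fit)
}

#' Fit a free-phase annual cosinor regression
#'
#' Ordinary least squares of a continuous outcome on the cosine and sine of
#' the within-year angular date plus covariates:
#' \deqn{y = \beta_0 + \beta_c \cos\theta + \beta_s \sin\theta +
#'       \gamma^T z + \epsilon.}
#' Including both quadrature terms leaves the phase free, so the acrophase
#' can fall at any calendar date.  Rhythmicity is tested by the 2-df nested
#' F-test against the model without the quadrature pair.  When a cohort
#' column with more than one level is supplied it enters as a fixed effect.
#'
#' @param data data frame, one row per participant-assessment.  Rows with
#'   missing values in any used column are dropped (complete-case) and the
#'   count is recorded in `n_dropped`.
#' @param outcome name of the continuous outcome column.
#' @param covariates character vector of covariate column names (numeric or
#'   factor; e.g. `c("age_years", "sex", "education_years")`).
#' @param date_col name of the assessment-date column.
#' @param period_days rhythm period (default 365.25).
#' @param cohort_col optional cohort column, added as a fixed effect when it
#'   has more than one level in the analysis sample.
#' @param sd_ref reference SD for the standardized amplitude; defaults to the
#'   SD of the outcome over the analysis sample.  Override to standardize by
#'   a baseline SD when fitting a non-baseline wave.
#' @param id_col optional participant-identifier column, used for
#'   participant-level bootstrap resampling.
#' @return an object of class `seasonal_fit`: coefficients, amplitude,
#'   acrophase/nadir (day of year), standardized amplitude, F-test of
#'   rhythmicity, residual SD, and the data needed to bootstrap.
#' @seealso [rhythm_test()], [bootstrap_ci()], [age_equivalent()]
#' @export
fit_cosinor <- function(data, outcome, covariates = character(),
                        date_col = "assess_date", period_days = 365.25,
                        cohort_col = NULL, sd_ref = NULL, id_col = NULL) {
  fr <- .cosinor_frame(data, outcome, covariates, date_col, period_days,
                       cohort_col,
                       extra_cols = if (is.null(id_col)) character() else id_col)
  d <- fr$data
  if (nrow(d) < 10L) stop("fewer than 10 complete rows (", nrow(d), ")")
  y <- d[[outcome]]
  if (all(!is.finite(y))) stop("outcome '", outcome, "' has no finite values")

  rhs_red <- if (length(fr$terms)) paste(fr$terms, collapse = " + ") else "1"
  f_full <- stats::as.formula(paste0(
    "`", outcome, "` ~ .cos + .sin + ", rhs_red))
  f_red <- stats::as.formula(paste0("`", outcome, "` ~ ", rhs_red))
  fit_full <- stats::lm(f_full, data = d)
  .check_full_rank(fit_full)
  fit_red <- stats::lm(f_red, data = d)

  an <- stats::anova(fit_red, fit_full)
  f_stat <- an[["F"]][2L]
  df_num <- as.integer(an[["Df"]][2L])
  df_den <- stats::df.residual(fit_full)
  p_rhythm <- an[["Pr(>F)"]][2L]
  if (df_den <= 0) stop("no residual degrees of freedom")
  if (stats::var(y) == 0 || !is.finite(f_stat)) {
    # constant outcome: no variance for the cosine pair to explain
    f_stat <- 0
    p_rhythm <- 1
  }

  co <- stats::coef(fit_full)
  aa <- amplitude_acrophase(co[[".cos"]], co[[".sin"]])
  sd_ref_supplied <- !is.null(sd_ref)
  if (!sd_ref_supplied) sd_ref <- stats::sd(y)
  # a constant outcome has no SD to standardize by; report NA, not an error
  amp_std <- if (is.finite(sd_ref) && sd_ref > 0)
    standardized_amplitude(aa$amplitude, sd_ref) else NA_real_
  acro_doy <- angle_to_doy(aa$acrophase_rad, period_days)
  nadir_doy <- angle_to_doy(aa$acrophase_rad + pi, period_days)
  cov_betas <- co[setdiff(names(co), c("(Intercept)", ".cos", ".sin"))]

  structure(list(
    beta_cos = unname(co[[".cos"]]),
    beta_sin = unname(co[[".sin"]]),
    covariate_betas = cov_betas,
    intercept = unname(co[["(Intercept)"]]),
    amplitude = aa$amplitude,
    acrophase_rad = aa$acrophase_rad,
    acrophase_date = acro_doy,
    nadir_date = nadir_doy,
    amplitude_std = amp_std,
    sd_ref = sd_ref,
    f_stat = f_stat, df_num = df_num, df_den = df_den, p_rhythm = p_rhythm,
    sigma = stats::sigma(fit_full),
    n_used = nrow(d), n_dropped = fr$n_dropped,
    amplitude_ci = NULL, amplitude_std_ci = NULL,
    age_equiv_years = NULL, age_equiv_ci = NULL,
    outcome = outcome, covariates = covariates, date_col = date_col,
    cohort_col = cohort_col, id_col = id_col, period_days = period_days,
    sd_ref_fixed = sd_ref_supplied,
    data = d[unique(c(outcome, date_col, covariates, cohort_col, id_col))],
    lm_full = fit_full
  ), class = "seasonal_fit")
}

#' @export
print.seasonal_fit <- function(x, ...) {
  cat("Cosinor fit:", x$outcome, "~ cos + sin",
      if (length(x$covariates)) paste("+", paste(x$covariates, collapse = " + ")),
      "\n")
  cat(sprintf("  n = %d (dropped %d incomplete)\n", x$n_used, x$n_dropped))
  cat(sprintf("  amplitude       %.4f (%.3f SD)\n", x$amplitude, x$amplitude_std))
  cat(sprintf("  acrophase       day %.1f   nadir day %.1f\n",
              x$acrophase_date, x$nadir_date))
  cat(sprintf("  rhythmicity     F(%d, %d) = %.3f, p = %.4g\n",
              x$df_num, x$df_den, x$f_stat, x$p_rhythm))
  if (!is.null(x$amplitude_ci))
    cat(sprintf("  amplitude 95%% CI [%.4f, %.4f]\n",
                x$amplitude_ci[1], x$amplitude_ci[2]))
  invisible(x)
}

#' Nested F-test of seasonal rhythmicity
#'
#' Recomputes the 2-df F-test comparing the full cosinor model against the
#' reduced model with both quadrature terms removed, from the data stored in
#' the fit.  Equivalent to the test already carried in the `seasonal_fit`,
#' exposed so that the statistic can be recomputed or audited.
#'
#' @param fit a `seasonal_fit` from [fit_cosinor()].
#' @return list with `f_stat`, `df_num` (= 2), `df_den`, `p`.
#' @export
rhythm_test <- function(fit) {
  stopifnot(inherits(fit, "seasonal_fit"))
  refit <- fit_cosinor(fit$data, fit$outcome, fit$covariates, fit$date_col,
                       fit$period_days, cohort_col = fit$cohort_col)
  list(f_stat = refit$f_stat, df_num = refit$df_num,
       df_den = refit$df_den, p = refit$p_rhythm)
}

#' Seasonal effect expressed as an equivalent difference in years of age
#'
#' Divides the fitted peak-to-trough cognitive difference (twice the
#' amplitude) by the absolute age slope from the same model, giving the age
#' difference whose cross-sectional cognitive effect matches the seasonal
#' swing.
#'
#' @param fit a `seasonal_fit` whose covariates include an age term.
#' @param age_col name of the age covariate (default `"age_years"`).
#' @param tol the age slope is treated as degenerate when its absolute value
#'   is below `tol`; the conversion is then flagged undefined.
#' @return list with `years` and the `beta_age` used.
#' @export
age_equivalent <- function(fit, age_col = "age_years", tol = 1e-8) {
  stopifnot(inherits(fit, "seasonal_fit"))
  if (!age_col %in% names(fit$covariate_betas))
    stop("age_equivalent: no '", age_col, "' coefficient in the fit")
  b_age <- fit$covariate_betas[[age_col]]
  if (abs(b_age) < tol)
    stop("age_equivalent: |beta_age| < ", tol,
         "; age-equivalence undefined for this fit")
  list(years = 2 * fit$amplitude / abs(b_age), beta_age = b_age)
}

#' Percentile bootstrap intervals for cosinor-derived quantities
#'
#' Case-resampling bootstrap at the participant level (rows, when no id
#' column is present): each replicate resamples participants with
#' replacement, refits the cosinor, and records amplitude, standardized
#' amplitude, and (when an age covariate is present) the age-equivalent
#' years.  Intervals are the 2.5/97.5 percentiles.  Rank-deficient
#' resamples are redrawn, up to a cap, with a count reported.
#'
#' @param fit a `seasonal_fit`.
#' @param B number of bootstrap replicates (>= 200; default 1000).
#' @param seed integer seed; fixed seed gives identical intervals.
#' @param conf confidence level (default 0.95).
#' @param age_col age covariate name for the age-equivalence ratio, or NULL
#'   to skip it.
#' @return the fit, with `amplitude_ci`, `amplitude_std_ci`, and (if
#'   computed) `age_equiv_years`/`age_equiv_ci` filled in; the bootstrap
#'   draws are attached as attribute `"boot"`.
#' @export
bootstrap_ci <- function(fit, B = 1000L, seed = NULL, conf = 0.95,
                         age_col = if ("age_years" %in% fit$covariates) "age_years" else NULL) {
  stopifnot(inherits(fit, "seasonal_fit"))
  if (B < 200L) stop("bootstrap_ci: B must be >= 200")
  if (!is.null(seed)) set.seed(seed)
  d <- fit$data
  if (!is.null(fit$id_col)) {
    ids <- split(seq_len(nrow(d)), d[[fit$id_col]])
  } else {
    ids <- as.list(seq_len(nrow(d)))
  }
  n_id <- length(ids)
  do_age <- !is.null(age_col) && age_col %in% names(fit$covariate_betas)
  amp <- amp_std <- age_eq <- numeric(B)
  redraws <- 0L
  for (b in seq_len(B)) {
    for (attempt in seq_len(20L)) {
      rows <- unlist(ids[sample.int(n_id, n_id, replace = TRUE)],
                     use.names = FALSE)
      rb <- tryCatch(
        fit_cosinor(d[rows, , drop = FALSE], fit$outcome, fit$covariates,
                    fit$date_col, fit$period_days, cohort_col = fit$cohort_col,
                    sd_ref = if (fit$sd_ref_fixed) fit$sd_ref else NULL),
        error = function(e) NULL)
      if (!is.null(rb)) break
      redraws <- redraws + 1L
    }
    if (is.null(rb)) stop("bootstrap_ci: resample retry cap exceeded")
    amp[b] <- rb$amplitude
    amp_std[b] <- rb$amplitude_std
    if (do_age)
      age_eq[b] <- tryCatch(age_equivalent(rb, age_col)$years,
                            error = function(e) NA_real_)
  }
  qs <- c((1 - conf) / 2, 1 - (1 - conf) / 2)
  fit$amplitude_ci <- unname(stats::quantile(amp, qs))
  fit$amplitude_std_ci <- unname(stats::quantile(amp_std, qs))
  if (do_age) {
    fit$age_equiv_years <- age_equivalent(fit, age_col)$years
    fit$age_equiv_ci <- unname(stats::quantile(age_eq, qs, na.rm = TRUE))
  }
  attr(fit, "boot") <- list(amplitude = amp, amplitude_std = amp_std,
                            age_equiv = if (do_age) age_eq else NULL,
                            redraws = redraws, B = B)
  fit
}

#' One-row summary of a cosinor fit, suitable for a TSV report
#'
#' @param fit a `seasonal_fit`.
#' @return one-row data frame with n, coefficients, amplitude, standardized
#'   amplitude, acrophase/nadir days, F, p, and CI bounds when present.
#' @export
fit_report_row <- function(fit) {
  stopifnot(inherits(fit, "seasonal_fit"))
  data.frame(
    outcome = fit$outcome, n_used = fit$n_used, n_dropped = fit$n_dropped,
    beta_cos = fit$beta_cos, beta_sin = fit$beta_sin,
    amplitude = fit$amplitude, amplitude_std = fit$amplitude_std,
    acrophase_date = fit$acrophase_date, nadir_date = fit$nadir_date,
    f_stat = fit$f_stat, df_num = fit$df_num, df_den = fit$df_den,
    p_rhythm = fit$p_rhythm,
    amplitude_ci_lo = if (is.null(fit$amplitude_ci)) NA_real_ else fit$amplitude_ci[1],
    amplitude_ci_hi = if (is.null(fit$amplitude_ci)) NA_real_ else fit$amplitude_ci[2],
    stringsAsFactors = FALSE)
}
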
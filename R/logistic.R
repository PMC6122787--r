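#' Combine an NCI/MCI/dementia diagnosis into the binary positive class
#'
#' @param diagnosis character or factor with levels among
#'   `"NCI"`, `"MCI"`, `"dementia"` (case-insensitive).
#' @return integer 0/1; MCI or dementia -> 1.
#' @export
mci_or_dementia <- function(diagnosis) {
  dx <- tolower(as.character(diagnosis))
  bad <- !dx %in% c("nci", "mci", "dementia") & !is.na(dx)
  if (any(bad))
    stop("mci_or_dementia: unknown diagnosis value(s): ",
         paste(unique(dx[bad]), collapse = ", "))
  ifelse(is.na(dx), NA_integer_, as.integer(dx %in% c("mci", "dementia")))
}

.check_binary_outcome <- function(y, what) {
  if (!all(y %in% c(0, 1))) stop(what, ": outcome must be coded 0/1")
  if (sum(y == 1) < 10L) stop(what, ": fewer than 10 events")
  if (sum(y == 0) < 1L) stop(what, ": no non-events")
  invisible(TRUE)
}

.check_separation <- function(fit, what) {
  if (!fit$converged)
    stop(what, ": IRLS did not converge after ", fit$iter, " iterations")
  co <- stats::coef(fit)
  big <- names(co)[is.finite(co) & abs(co) > 15]
  if (length(big))
    stop(what, ": apparent complete separation (coefficient(s) ",
         paste(big, collapse = ", "), " diverged)")
  invisible(fit)
}

#' Logistic model of diagnosis odds on the continuous seasonal cosine
#'
#' Maximum-likelihood logistic regression of a binary outcome (MCI or
#' dementia vs no cognitive impairment) on the cosine/sine quadrature pair
#' of the assessment date plus covariates, with a 2-df likelihood-ratio
#' test against the model without the seasonal pair.
#'
#' @inheritParams fit_cosinor
#' @param outcome name of the 0/1 outcome column.
#' @return object of class `seasonal_logistic_fit`: `beta_cos`, `beta_sin`,
#'   `covariate_betas`, `deviance_delta` (full minus reduced, <= 0),
#'   `p_lrt`, `n_cases`, `n_total`, `converged`.
#' @export
fit_seasonal_logistic <- function(data, outcome, covariates = character(),
                                  date_col = "assess_date",
                                  period_days = 365.25, cohort_col = NULL) {
  fr <- .cosinor_frame(data, outcome, covariates, date_col, period_days,
                       cohort_col)
  d <- fr$data
  y <- d[[outcome]]
  .check_binary_outcome(y, "fit_seasonal_logistic")
  rhs_red <- if (length(fr$terms)) paste(fr$terms, collapse = " + ") else "1"
  full <- stats::glm(
    stats::as.formula(paste0("`", outcome, "` ~ .cos + .sin + ", rhs_red)),
    family = stats::binomial(), data = d)
  .check_separation(full, "fit_seasonal_logistic")
  .check_full_rank(full)
  red <- stats::glm(
    stats::as.formula(paste0("`", outcome, "` ~ ", rhs_red)),
    family = stats::binomial(), data = d)
  dev_delta <- full$deviance - red$deviance      # <= 0
  p_lrt <- stats::pchisq(-dev_delta, df = 2, lower.tail = FALSE)
  co <- stats::coef(full)
  aa <- amplitude_acrophase(co[[".cos"]], co[[".sin"]])
  structure(list(
    beta_cos = unname(co[[".cos"]]), beta_sin = unname(co[[".sin"]]),
    covariate_betas = co[setdiff(names(co), c("(Intercept)", ".cos", ".sin"))],
    amplitude_logodds = aa$amplitude,
    acrophase_date = angle_to_doy(aa$acrophase_rad, period_days),
    deviance_delta = dev_delta, p_lrt = p_lrt,
    n_cases = sum(y == 1), n_total = length(y), n_dropped = fr$n_dropped,
    converged = full$converged, glm_full = full
  ), class = "seasonal_logistic_fit")
}

#' @export
print.seasonal_logistic_fit <- function(x, ...) {
  cat("Seasonal logistic fit (continuous cosine):\n")
  cat(sprintf("  cases %d / %d\n", x$n_cases, x$n_total))
  cat(sprintf("  deviance change (full - reduced) = %.2f, LRT p = %.4g\n",
              x$deviance_delta, x$p_lrt))
  invisible(x)
}

#' Winter/spring vs summer/fall odds ratio for MCI/dementia
#'
#' Logistic regression of a binary diagnosis on categorical season
#' (January-June vs July-December reference), optionally covariate-adjusted,
#' with a Wald 95% CI for the odds ratio and a 1-df likelihood-ratio test
#' against the model without the season term.  With no covariates the OR
#' equals the 2x2 cross-product ratio.
#'
#' @inheritParams fit_seasonal_logistic
#' @param covariates covariate column names, or `character()`/`NULL` for the
#'   unadjusted model.
#' @param conf confidence level for the Wald interval.
#' @return object of class `season_or_fit`: `or`, `or_ci`, `p_wald`,
#'   `deviance_delta`, `p_lrt`, stratum counts.
#' @export
season_odds_ratio <- function(data, outcome, covariates = character(),
                              date_col = "assess_date", cohort_col = NULL,
                              conf = 0.95) {
  if (is.null(covariates)) covariates <- character()
  fr <- .cosinor_frame(data, outcome, covariates, date_col, 365.25, cohort_col)
  d <- fr$data
  y <- d[[outcome]]
  .check_binary_outcome(y, "season_odds_ratio")
  d$.season <- categorical_season(d[[date_col]])
  tab <- table(d$.season, factor(y, levels = c(0, 1)))
  if (any(tab == 0))
    stop("season_odds_ratio: a season stratum lacks events or non-events")
  rhs_red <- if (length(fr$terms)) paste(fr$terms, collapse = " + ") else "1"
  full <- stats::glm(
    stats::as.formula(paste0("`", outcome, "` ~ .season + ", rhs_red)),
    family = stats::binomial(), data = d)
  .check_separation(full, "season_odds_ratio")
  .check_full_rank(full)
  red <- stats::glm(
    stats::as.formula(paste0("`", outcome, "` ~ ", rhs_red)),
    family = stats::binomial(), data = d)
  sm <- summary(full)$coefficients[".seasonwinter_spring", ]
  zq <- stats::qnorm(1 - (1 - conf) / 2)
  dev_delta <- full$deviance - red$deviance
  ep5 <- sum(y == 1) / length(stats::coef(full))
  if (ep5 < 5)
    warning("season_odds_ratio: fewer than 5 events per parameter (",
            round(ep5, 1), ")")
  structure(list(
    or = exp(unname(sm["Estimate"])),
    or_ci = exp(unname(sm["Estimate"]) + c(-1, 1) * zq * unname(sm["Std. Error"])),
    log_or = unname(sm["Estimate"]), se_log_or = unname(sm["Std. Error"]),
    p_wald = unname(sm["Pr(>|z|)"]),
    deviance_delta = dev_delta,
    p_lrt = stats::pchisq(-dev_delta, df = 1, lower.tail = FALSE),
    counts = tab, n_total = length(y), n_dropped = fr$n_dropped
  ), class = "season_or_fit")
}

#' @export
print.season_or_fit <- function(x, ...) {
  cat("Winter/spring (Jan-Jun) vs summer/fall (Jul-Dec) odds of diagnosis:\n")
  cat(sprintf("  OR %.3f [%.3f, %.3f], Wald p = %.4g, LRT p = %.4g\n",
              x$or, x$or_ci[1], x$or_ci[2], x$p_wald, x$p_lrt))
  invisible(x)
}
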
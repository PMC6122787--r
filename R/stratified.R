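#' Cosinor model allowing a binary group to shift level and rhythmicity
#'
#' Augments the pooled cosinor with a main effect of a binary group (for
#' example, pathological AD at autopsy) and group-by-cosine and
#' group-by-sine interaction terms:
#' \deqn{y = \beta_0 + \beta_c \cos\theta + \beta_s \sin\theta + \delta g +
#'       \eta_c\, g\cos\theta + \eta_s\, g\sin\theta + \gamma^T z + \epsilon.}
#' The group difference in *level* is the t-test on \eqn{\delta}; the group
#' difference in *rhythmicity* is the joint 2-df F-test on
#' \eqn{(\eta_c, \eta_s)}.  Per-group amplitude and acrophase are derived
#' from the group-specific quadrature coefficients.
#'
#' @inheritParams fit_cosinor
#' @param group name of a binary (0/1, logical, or 2-level factor) column.
#' @return object of class `group_modulated_fit`: pooled-style coefficients,
#'   `group_level_beta`/`group_level_se`/`group_level_p`,
#'   `group_rhythm_f`/`group_rhythm_p`, and a per-group table of
#'   amplitude/acrophase.
#' @export
fit_group_modulated <- function(data, outcome, group,
                                covariates = character(),
                                date_col = "assess_date",
                                period_days = 365.25, cohort_col = NULL) {
  fr <- .cosinor_frame(data, outcome, covariates, date_col, period_days,
                       cohort_col, extra_cols = group)
  d <- fr$data
  g <- d[[group]]
  if (is.factor(g) || is.character(g)) {
    g <- factor(g)
    if (nlevels(g) != 2L) stop("group '", group, "' must have exactly 2 levels")
    g <- as.integer(g) - 1L
  } else if (is.logical(g)) {
    g <- as.integer(g)
  }
  if (!all(g %in% c(0, 1))) stop("group '", group, "' must be binary")
  if (length(unique(g)) < 2L)
    stop("group '", group, "' takes a single value in the analysis sample")
  if (min(table(g)) < 10L) stop("each group needs >= 10 complete rows")
  d$.g <- g
  rhs_cov <- if (length(fr$terms)) paste("+", paste(fr$terms, collapse = " + ")) else ""
  full <- stats::lm(stats::as.formula(paste0(
    "`", outcome, "` ~ .cos + .sin + .g + .g:.cos + .g:.sin", rhs_cov)),
    data = d)
  .check_full_rank(full)
  no_int <- stats::lm(stats::as.formula(paste0(
    "`", outcome, "` ~ .cos + .sin + .g", rhs_cov)), data = d)
  an <- stats::anova(no_int, full)
  co <- stats::coef(full)
  sm <- summary(full)$coefficients
  int_cos <- grep("^\\.cos:\\.g$|^\\.g:\\.cos$", names(co), value = TRUE)
  int_sin <- grep("^\\.sin:\\.g$|^\\.g:\\.sin$", names(co), value = TRUE)
  b_c0 <- co[[".cos"]]; b_s0 <- co[[".sin"]]
  b_c1 <- b_c0 + co[[int_cos]]; b_s1 <- b_s0 + co[[int_sin]]
  aa0 <- amplitude_acrophase(b_c0, b_s0)
  aa1 <- amplitude_acrophase(b_c1, b_s1)
  per_group <- data.frame(
    group = c(0L, 1L),
    beta_cos = c(b_c0, b_c1), beta_sin = c(b_s0, b_s1),
    amplitude = c(aa0$amplitude, aa1$amplitude),
    acrophase_date = angle_to_doy(c(aa0$acrophase_rad, aa1$acrophase_rad),
                                  period_days),
    n = as.vector(table(g)))
  structure(list(
    group = group,
    group_level_beta = unname(co[[".g"]]),
    group_level_se = unname(sm[".g", "Std. Error"]),
    group_level_p = unname(sm[".g", "Pr(>|t|)"]),
    group_rhythm_f = an[["F"]][2L], group_rhythm_df = an[["Df"]][2L],
    group_rhythm_p = an[["Pr(>F)"]][2L],
    per_group = per_group,
    beta_cos = b_c0, beta_sin = b_s0,
    covariate_betas = co[setdiff(names(co),
      c("(Intercept)", ".cos", ".sin", ".g", int_cos, int_sin))],
    n_used = nrow(d), n_dropped = fr$n_dropped,
    lm_full = full
  ), class = "group_modulated_fit")
}

#' @export
print.group_modulated_fit <- function(x, ...) {
  cat("Group-modulated cosinor fit (group =", x$group, ")\n")
  cat(sprintf("  level difference  %.3f (SE %.3f), p = %.4g\n",
              x$group_level_beta, x$group_level_se, x$group_level_p))
  cat(sprintf("  rhythm difference F(%d) = %.3f, p = %.4g\n",
              x$group_rhythm_df, x$group_rhythm_f, x$group_rhythm_p))
  print(x$per_group, row.names = FALSE)
  invisible(x)
}

#' Cosinor fits under a sweep of confounder-adjustment sets
#'
#' Refits the cosinor under each adjustment set (base covariates plus the
#' listed confounders), each with its own complete-case sample, and reports
#' amplitude, standardized amplitude, acrophase, p and n per set — the
#' robustness-table layout used to show that estimates are stable to
#' adjustment for test time, depression, sleep, activity, or TSH.
#'
#' @inheritParams fit_cosinor
#' @param base_covariates covariates present in every model.
#' @param confounder_sets named list of character vectors; each element is a
#'   set of additional adjustment columns (may be `character()` for the base
#'   model).
#' @return data frame, one row per adjustment set.
#' @export
confounder_sweep <- function(data, outcome, base_covariates,
                             confounder_sets, date_col = "assess_date",
                             period_days = 365.25, cohort_col = NULL,
                             sd_ref = NULL) {
  if (!length(confounder_sets)) stop("confounder_sweep: empty set list")
  if (is.null(names(confounder_sets)))
    names(confounder_sets) <- vapply(confounder_sets, function(s)
      if (length(s)) paste(s, collapse = "+") else "base", "")
  rows <- lapply(names(confounder_sets), function(nm) {
    fit <- fit_cosinor(data, outcome,
                       unique(c(base_covariates, confounder_sets[[nm]])),
                       date_col, period_days, cohort_col, sd_ref = sd_ref)
    cbind(data.frame(adjustment = nm, stringsAsFactors = FALSE),
          fit_report_row(fit))
  })
  do.call(rbind, rows)
}

#' Single-modifier interaction checks for a seasonal rhythm
#'
#' For each candidate effect modifier, fits one model adding
#' modifier-by-cosine and modifier-by-sine interactions to the base cosinor
#' and reports the joint interaction p-value, one model per modifier.
#'
#' @inheritParams fit_cosinor
#' @param modifiers character vector of modifier column names.
#' @return data frame with one row per modifier: F, df, p of the joint
#'   interaction test.
#' @export
interaction_checks <- function(data, outcome, covariates, modifiers,
                               date_col = "assess_date",
                               period_days = 365.25, cohort_col = NULL) {
  rows <- lapply(modifiers, function(m) {
    fr <- .cosinor_frame(data, outcome, unique(c(covariates, m)), date_col,
                         period_days, cohort_col)
    d <- fr$data
    rhs <- paste(fr$terms, collapse = " + ")
    full <- stats::lm(stats::as.formula(paste0(
      "`", outcome, "` ~ .cos + .sin + ", rhs,
      " + `", m, "`:.cos + `", m, "`:.sin")), data = d)
    base <- stats::lm(stats::as.formula(paste0(
      "`", outcome, "` ~ .cos + .sin + ", rhs)), data = d)
    an <- stats::anova(base, full)
    data.frame(modifier = m, f_stat = an[["F"]][2L], df = an[["Df"]][2L],
               p_interaction = an[["Pr(>F)"]][2L], n_used = nrow(d),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
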
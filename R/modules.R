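## Gene co-expression module summarization, rhythm/cognition scans,
## permutation-based family-wise adjustment, and candidate selection.

.module_list <- function(modules) {
  if (is.data.frame(modules)) {
    if (!all(c("gene", "module") %in% names(modules)))
      stop("module definitions need 'gene' and 'module' columns")
    split(as.character(modules$gene), as.character(modules$module))
  } else if (is.list(modules)) {
    if (is.null(names(modules))) stop("module list must be named")
    lapply(modules, as.character)
  } else stop("modules must be a data frame or named list")
}

## Reorder meta rows to the columns of a score/expression matrix.
.align_meta <- function(mat, meta, sample_col = "sample_id") {
  if (sample_col %in% names(meta)) {
    idx <- match(colnames(mat), as.character(meta[[sample_col]]))
    if (anyNA(idx))
      stop("samples missing from metadata: ",
           paste(utils::head(colnames(mat)[is.na(idx)], 5L), collapse = ", "))
    meta <- meta[idx, , drop = FALSE]
  } else if (nrow(meta) != ncol(mat)) {
    stop("metadata rows (", nrow(meta), ") do not match samples (",
         ncol(mat), ") and no '", sample_col, "' column is present")
  }
  meta
}

#' Per-gene z-scoring of an expression matrix
#'
#' Centers each gene (row) at its mean across samples and scales by its
#' sample standard deviation.  Genes with zero variance cannot be scaled
#' and are dropped with a warning.
#'
#' @param mat numeric matrix, genes x samples, with unique rownames.
#' @return z-scored matrix (possibly with fewer rows); the dropped gene
#'   names are attached as attribute `"dropped"`.
#' @export
normalize_expression <- function(mat) {
  stopifnot(is.matrix(mat), is.numeric(mat))
  if (is.null(rownames(mat)) || anyDuplicated(rownames(mat)))
    stop("normalize_expression: rownames must be unique gene identifiers")
  if (anyNA(mat)) stop("normalize_expression: matrix contains missing values")
  sds <- apply(mat, 1L, stats::sd)
  drop <- sds == 0 | !is.finite(sds)
  if (any(drop)) {
    warning("dropping ", sum(drop), " zero-variance gene(s)")
    mat <- mat[!drop, , drop = FALSE]
    sds <- sds[!drop]
  }
  z <- (mat - rowMeans(mat)) / sds
  attr(z, "dropped") <- names(drop)[drop]
  z
}

#' Summarize module expression as the mean of member-gene z-scores
#'
#' @param z z-scored genes x samples matrix from [normalize_expression()].
#' @param modules module definitions: data frame with `gene`/`module`
#'   columns, or a named list of gene-id vectors.
#' @param min_frac minimum fraction of a module's genes that must be present
#'   in `z`; modules below this are skipped with a warning.
#' @return modules x samples matrix of mean normalized expression
#'   (the `ModuleScoreMatrix`).
#' @export
summarize_modules <- function(z, modules, min_frac = 0.5) {
  ml <- .module_list(modules)
  rows <- lapply(names(ml), function(m) {
    present <- intersect(ml[[m]], rownames(z))
    if (length(present) < max(1L, ceiling(min_frac * length(ml[[m]])))) {
      warning("module ", m, ": only ", length(present), "/", length(ml[[m]]),
              " genes present; skipped")
      return(NULL)
    }
    colMeans(z[present, , drop = FALSE])
  })
  names(rows) <- names(ml)
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) stop("no module had sufficient gene overlap")
  out <- do.call(rbind, rows)
  colnames(out) <- colnames(z)
  out
}

#' Seasonal rhythm scan over module scores
#'
#' Fits the covariate-adjusted cosinor ([fit_cosinor()]) to each module
#' score against the (death-)date in the sample metadata and collects
#' amplitude, standardized amplitude, acrophase and the raw rhythmicity p.
#'
#' @param scores modules x samples score matrix.
#' @param meta data frame of sample metadata; either one row per score
#'   column in order, or carrying a `sample_id` column matching the score
#'   matrix's column names.
#' @param covariates covariate column names in `meta` (e.g. age at death,
#'   sex, education, death-hour bin, PMI, batch, RIN).
#' @param date_col date column in `meta` (default `"death_date"`).
#' @param period_days rhythm period in days.
#' @return data frame, one row per module (raw, unadjusted p-values).
#' @export
module_rhythm_scan <- function(scores, meta, covariates = character(),
                               date_col = "death_date",
                               period_days = 365.25) {
  meta <- .align_meta(scores, meta)
  rows <- lapply(rownames(scores), function(m) {
    d <- cbind(data.frame(.score = scores[m, ]), meta)
    fit <- fit_cosinor(d, ".score", covariates, date_col, period_days)
    data.frame(module = m, n = fit$n_used,
               amplitude = fit$amplitude, amplitude_std = fit$amplitude_std,
               acrophase_date = fit$acrophase_date,
               nadir_date = fit$nadir_date,
               f_stat = fit$f_stat, p_raw = fit$p_rhythm,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Association of cognition proximate to death with module expression
#'
#' One OLS per module: cognition at the last visit as a linear function of
#' the module score, adjusted for covariates.
#'
#' @inheritParams module_rhythm_scan
#' @param cognition_col column of `meta` holding cognition proximate to
#'   death.
#' @return data frame per module: `beta`, `t_stat`, `p_raw`, `n`.
#' @export
cognition_association_scan <- function(scores, meta, cognition_col,
                                       covariates = character()) {
  meta <- .align_meta(scores, meta)
  rows <- lapply(rownames(scores), function(m) {
    d <- cbind(data.frame(.score = scores[m, ]), meta)
    keep <- stats::complete.cases(d[c(".score", cognition_col, covariates)])
    d <- d[keep, , drop = FALSE]
    if (nrow(d) < 10L) stop("module ", m, ": fewer than 10 matched samples")
    rhs <- paste(c(".score", covariates), collapse = " + ")
    fit <- stats::lm(stats::as.formula(paste0("`", cognition_col, "` ~ ", rhs)),
                     data = d)
    sm <- summary(fit)$coefficients
    data.frame(module = m, beta = sm[".score", "Estimate"],
               t_stat = sm[".score", "t value"],
               p_raw = sm[".score", "Pr(>|t|)"], n = nrow(d),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

## Orthonormal basis of a design matrix (for fast repeated RSS).
.qbasis <- function(X) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("rank-deficient design in permutation scan")
  qr.Q(qrX)[, seq_len(qrX$rank), drop = FALSE]
}

## Rhythm F statistics for every column of score matrix S (samples x modules)
## given orthonormal bases of the full and reduced designs.
.rhythm_F <- function(S, Qf, Qr, df_den) {
  tot <- colSums(S^2)
  rss_f <- tot - colSums((crossprod(Qf, S))^2)
  rss_r <- tot - colSums((crossprod(Qr, S))^2)
  ((rss_r - rss_f) / 2) / (rss_f / df_den)
}

## |t| statistics for cognition ~ score + covariates via Frisch-Waugh:
## residualize both on the covariate design and use the partial correlation.
.cognition_t <- function(S, y_res, Qz, df) {
  S_res <- S - Qz %*% crossprod(Qz, S)
  r <- as.vector(crossprod(S_res, y_res)) /
    sqrt(colSums(S_res^2) * sum(y_res^2))
  abs(r) * sqrt(df) / sqrt(pmax(1 - r^2, .Machine$double.eps))
}

#' Permutation-based family-wise adjusted p-values for module statistics
#'
#' Generates null datasets by permuting the gene-to-module assignment
#' vector (module sizes preserved), recomputes module scores and the chosen
#' statistic for each permutation, and adjusts each observed module
#' statistic by the distribution of the *maximum* statistic across modules
#' (single-step max-statistic family-wise control), with the add-one
#' correction \eqn{(r+1)/(B+1)}.  A per-module unadjusted permutation p
#' (against the module's own null statistics) is returned alongside, and is
#' never larger than the adjusted p.  `statistic = "both"` computes the
#' rhythm-F and cognition-|t| families in one call.
#'
#' Null scheme per family: the cognition family permutes gene-to-module
#' labels (the study's stated scheme for that analysis); the rhythm family
#' defaults to permuting samples against the date design (`"dates"`), the
#' scheme of the companion expression study the rhythmicity adjustment
#' builds on.  At desk scale the planted modules occupy a much larger
#' fraction of the gene universe than in a full transcriptome, which makes
#' the label-permutation null for rhythmicity heavy-tailed; see the
#' methods vignette.  Either family can be forced onto either scheme with
#' `permute`.
#'
#' @param z z-scored genes x samples matrix.
#' @param modules module definitions (see [summarize_modules()]).
#' @param meta sample metadata (see [module_rhythm_scan()]).
#' @param statistic `"rhythm"` (cosinor F), `"cognition"` (|t| of the
#'   module-score coefficient), or `"both"`.
#' @param covariates covariate columns in `meta` for the rhythm design.
#' @param cognition_col,cognition_covariates cognition column and its
#'   adjustment set (defaults to `covariates`), required unless
#'   `statistic = "rhythm"`.
#' @param date_col date column in `meta`.
#' @param n_perm number of permutations (>= 100; the study default is
#'   10,000).
#' @param seed integer seed; results are deterministic given the seed.
#' @param permute NULL (per-family defaults: rhythm `"dates"`, cognition
#'   `"modules"`), or `"modules"`/`"dates"` to force one scheme for all
#'   requested families.
#' @param period_days rhythm period.
#' @return data frame per module with observed statistic(s), `p_perm`
#'   (own-statistic permutation p) and `p_adj` (max-statistic family-wise
#'   p); for `"both"`, columns are suffixed `_rhythm` and `_cognition`.
#' @export
permutation_adjust <- function(z, modules, meta,
                               statistic = c("rhythm", "cognition", "both"),
                               covariates = character(),
                               cognition_col = NULL,
                               cognition_covariates = covariates,
                               date_col = "death_date",
                               n_perm = 10000L, seed = NULL,
                               permute = NULL,
                               period_days = 365.25) {
  statistic <- match.arg(statistic)
  if (!is.null(permute))
    permute <- match.arg(permute, c("modules", "dates"))
  if (n_perm < 100L) stop("permutation_adjust: n_perm must be >= 100")
  if (statistic != "rhythm" && is.null(cognition_col))
    stop("cognition_col required for the cognition statistic")
  if (!is.null(seed)) set.seed(seed)
  meta <- .align_meta(z, meta)

  ml <- .module_list(modules)
  assignment <- rep(NA_character_, nrow(z))
  names(assignment) <- rownames(z)
  for (m in names(ml)) {
    present <- intersect(ml[[m]], rownames(z))
    assignment[present] <- m
  }
  mod_levels <- sort(names(ml))
  afac <- factor(assignment, levels = mod_levels)
  sizes <- table(afac)

  theta <- date_to_angle(meta[[date_col]], period_days)
  n <- ncol(z)
  do_rhythm <- statistic %in% c("rhythm", "both")
  do_cog <- statistic %in% c("cognition", "both")
  if (do_rhythm) {
    Xr <- stats::model.matrix(
      stats::as.formula(paste(c("~ 1", covariates), collapse = " + ")), meta)
    if (nrow(Xr) != n) stop("missing values in rhythm covariates")
    Xf <- cbind(Xr, .cos = cos(theta), .sin = sin(theta))
    Qf <- .qbasis(Xf); Qr <- .qbasis(Xr)
    df_den <- n - qr(Xf)$rank
  }
  if (do_cog) {
    Z <- stats::model.matrix(
      stats::as.formula(paste(c("~ 1", cognition_covariates), collapse = " + ")),
      meta)
    if (nrow(Z) != n) stop("missing values in cognition covariates")
    Qz <- .qbasis(Z)
    y <- meta[[cognition_col]]
    if (anyNA(y)) stop("missing values in '", cognition_col, "'")
    y_res <- y - Qz %*% crossprod(Qz, y)
    df_cog <- n - qr(Z)$rank - 1L
  }

  score_mat <- function(af) {
    keep <- !is.na(af)
    s <- rowsum(z[keep, , drop = FALSE], af[keep])   # modules x samples
    t(s / as.vector(table(af[keep])[rownames(s)]))   # samples x modules
  }
  stat_of <- function(S, which) {
    if (which == "rhythm") .rhythm_F(S, Qf, Qr, df_den)
    else .cognition_t(S, y_res, Qz, df_cog)
  }

  S_obs <- score_mat(afac)
  wanted <- c(if (do_rhythm) "rhythm", if (do_cog) "cognition")
  scheme_for <- function(w) {
    if (!is.null(permute)) permute
    else if (w == "rhythm") "dates" else "modules"
  }
  ## independent, seed-derived streams per family so that a standalone
  ## "rhythm" or "cognition" run reproduces the matching "both" columns
  offset <- c(rhythm = 0L, cognition = 1L)
  run_family <- function(w) {
    if (!is.null(seed)) set.seed(seed + offset[[w]])
    scheme <- scheme_for(w)
    obs <- stat_of(S_obs, w)
    own <- mx <- numeric(length(obs))
    for (b in seq_len(n_perm)) {
      S_b <- if (scheme == "modules")
        score_mat(afac[sample.int(length(afac))])
      else S_obs[sample.int(n), , drop = FALSE]
      st <- stat_of(S_b, w)
      own <- own + (st >= obs)
      mx <- mx + (max(st) >= obs)
    }
    list(obs = obs, p_perm = (own + 1) / (n_perm + 1),
         p_adj = (mx + 1) / (n_perm + 1))
  }
  out <- data.frame(module = colnames(S_obs), stringsAsFactors = FALSE)
  for (w in wanted) {
    fam <- run_family(w)
    suff <- if (statistic == "both") paste0("_", w) else ""
    out[[paste0("stat", suff)]] <- fam$obs
    out[[paste0("p_perm", suff)]] <- fam$p_perm
    out[[paste0("p_adj", suff)]] <- fam$p_adj
  }
  out
}

#' Phase concordance of a module rhythm with the cognition rhythm
#'
#' Classifies a module acrophase as in phase (circular distance to the
#' cognition acrophase within the window), antiphase (within the window of
#' the cognition nadir, half a period away), or neither.  The default
#' window is two months, period/6 = 60.875 days, with a strict `<=`
#' boundary.
#'
#' @param module_acrophase_date day-of-year acrophase(s) of module scores.
#' @param cognition_acrophase_date day-of-year acrophase of cognition.
#' @param window_days circular half-window in days.
#' @param period_days period in days.
#' @return factor with levels `in_phase`, `anti_phase`, `neither`.
#' @export
phase_concordance <- function(module_acrophase_date, cognition_acrophase_date,
                              window_days = 365.25 / 6,
                              period_days = 365.25) {
  d_acro <- circular_diff_days(module_acrophase_date,
                               cognition_acrophase_date, period_days)
  d_nadir <- circular_diff_days(module_acrophase_date,
                                cognition_acrophase_date + period_days / 2,
                                period_days)
  factor(ifelse(d_acro <= window_days, "in_phase",
         ifelse(d_nadir <= window_days, "anti_phase", "neither")),
         levels = c("in_phase", "anti_phase", "neither"))
}

#' Three-criterion selection of cognition-linked rhythmic modules
#'
#' A module is selected when (1) its rhythmicity is significant after
#' family-wise permutation adjustment, (2) its acrophase is in phase or
#' antiphase with the cognition rhythm (within the two-month window), and
#' (3) its association with cognition proximate to death is significant
#' after family-wise permutation adjustment.
#'
#' @param rhythm_scan output of [module_rhythm_scan()].
#' @param rhythm_adj rhythm rows of [permutation_adjust()] (columns
#'   `module`, `p_adj`).
#' @param cognition_scan output of [cognition_association_scan()].
#' @param cognition_adj cognition rows of [permutation_adjust()].
#' @param cognition_acrophase_date cognition acrophase (day of year).
#' @param window_days phase-concordance window (days).
#' @param alpha significance level on adjusted p-values.
#' @param period_days period in days.
#' @return `ModuleSelectionReport` data frame sorted by module id, with the
#'   three criterion flags and `selected_flag`.
#' @export
select_candidate_modules <- function(rhythm_scan, rhythm_adj,
                                     cognition_scan, cognition_adj,
                                     cognition_acrophase_date,
                                     window_days = 365.25 / 6,
                                     alpha = 0.05, period_days = 365.25) {
  stopifnot(setequal(rhythm_scan$module, cognition_scan$module),
            setequal(rhythm_scan$module, rhythm_adj$module),
            setequal(rhythm_scan$module, cognition_adj$module))
  m <- rhythm_scan[order(rhythm_scan$module), ]
  ra <- rhythm_adj[match(m$module, rhythm_adj$module), ]
  cs <- cognition_scan[match(m$module, cognition_scan$module), ]
  ca <- cognition_adj[match(m$module, cognition_adj$module), ]
  phase <- phase_concordance(m$acrophase_date, cognition_acrophase_date,
                             window_days, period_days)
  out <- data.frame(
    module = m$module,
    amplitude_std = m$amplitude_std,
    acrophase_date = m$acrophase_date,
    p_rhythm_adj = ra$p_adj,
    cognition_beta = cs$beta,
    p_cog_adj = ca$p_adj,
    phase = phase,
    in_phase_flag = phase %in% c("in_phase", "anti_phase"),
    stringsAsFactors = FALSE)
  out$selected_flag <- out$p_rhythm_adj < alpha & out$in_phase_flag &
    out$p_cog_adj < alpha
  out
}

#' Module-by-phenotype Spearman correlation grid
#'
#' Spearman correlations between each module score and each phenotype, with
#' two-sided p-values, Bonferroni correction across the full grid, and a
#' Fisher-z transform for heatmap display.  Cells with a constant variable
#' or fewer than `min_pairs` paired observations are marked undefined (NA).
#'
#' @param scores modules x samples score matrix.
#' @param phenotypes data frame of phenotype columns (one row per sample, in
#'   score-column order, or with a `sample_id` column).
#' @param min_pairs minimum paired observations per cell.
#' @param alpha family-wise level for the Bonferroni flag.
#' @return long data frame: module, phenotype, n, rho, z, p, p_bonf,
#'   significant.
#' @export
phenotype_correlation_grid <- function(scores, phenotypes, min_pairs = 10L,
                                       alpha = 0.05) {
  phenotypes <- .align_meta(scores, phenotypes)
  ph_cols <- setdiff(names(phenotypes), "sample_id")
  grid <- expand.grid(module = rownames(scores), phenotype = ph_cols,
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    s <- scores[grid$module[i], ]
    p <- phenotypes[[grid$phenotype[i]]]
    ok <- is.finite(s) & is.finite(p)
    n <- sum(ok)
    if (n < min_pairs || stats::sd(p[ok]) == 0 || stats::sd(s[ok]) == 0)
      return(data.frame(n = n, rho = NA_real_, z = NA_real_, p = NA_real_))
    ct <- suppressWarnings(
      stats::cor.test(s[ok], p[ok], method = "spearman", exact = FALSE))
    rho <- unname(ct$estimate)
    data.frame(n = n, rho = rho,
               z = atanh(min(max(rho, -1 + 1e-12), 1 - 1e-12)) * sqrt(n - 3),
               p = ct$p.value)
  })
  out <- cbind(grid, do.call(rbind, res))
  n_tests <- sum(!is.na(out$p))
  out$p_bonf <- pmin(out$p * n_tests, 1)
  out$significant <- !is.na(out$p_bonf) & out$p_bonf < alpha
  out
}

#' End-to-end module selection pipeline
#'
#' Convenience wrapper: z-scores the expression matrix, summarizes modules,
#' runs the rhythm and cognition scans, obtains family-wise adjusted
#' p-values from a single shared permutation stream, and applies the
#' three-criterion selection against the supplied cognition acrophase.
#'
#' @inheritParams permutation_adjust
#' @param mat raw genes x samples expression matrix.
#' @param cognition_acrophase_date day-of-year acrophase of cognition.
#' @param window_days phase window in days.
#' @param alpha adjusted-significance level.
#' @return list with `scores`, `rhythm_scan`, `cognition_scan`,
#'   `adjusted`, and the `selection` report.
#' @export
run_module_selection <- function(mat, modules, meta,
                                 covariates = character(),
                                 cognition_col = "cognition",
                                 cognition_covariates = covariates,
                                 date_col = "death_date",
                                 cognition_acrophase_date,
                                 n_perm = 10000L, seed = NULL,
                                 window_days = 365.25 / 6, alpha = 0.05,
                                 period_days = 365.25) {
  z <- normalize_expression(mat)
  scores <- summarize_modules(z, modules)
  meta_a <- .align_meta(scores, meta)
  rs <- module_rhythm_scan(scores, meta_a, covariates, date_col, period_days)
  cs <- cognition_association_scan(scores, meta_a, cognition_col,
                                   cognition_covariates)
  adj <- permutation_adjust(z, modules, meta_a, statistic = "both",
                            covariates = covariates,
                            cognition_col = cognition_col,
                            cognition_covariates = cognition_covariates,
                            date_col = date_col, n_perm = n_perm, seed = seed,
                            period_days = period_days)
  rhythm_adj <- data.frame(module = adj$module, p_adj = adj$p_adj_rhythm)
  cog_adj <- data.frame(module = adj$module, p_adj = adj$p_adj_cognition)
  sel <- select_candidate_modules(rs, rhythm_adj, cs, cog_adj,
                                  cognition_acrophase_date, window_days,
                                  alpha, period_days)
  list(scores = scores, rhythm_scan = rs, cognition_scan = cs,
       adjusted = adj, selection = sel)
}
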
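## Independent oracles used across the suite.  These deliberately avoid the
## package's own code paths (closed-form atan2 amplitude, qr-based F, sorted
## interval search) so agreement is evidence, not tautology.

## Brute-force cosinor: grid-search the phase over n_grid steps, fitting
## outcome ~ cos(theta - phi) + covariates at each step and maximizing R^2;
## optionally refine the best bracket with a continuous 1-d optimizer.
grid_cosinor_oracle <- function(data, outcome, covariates = character(),
                                date_col = "assess_date", n_grid = 3650L,
                                refine = FALSE) {
  theta <- date_to_angle(data[[date_col]])
  y <- data[[outcome]]
  Xcov <- if (length(covariates))
    as.matrix(data[covariates]) else NULL
  rsq_at <- function(phi) {
    X <- cbind(1, cos(theta - phi), Xcov)
    f <- stats::lm.fit(X, y)
    1 - sum(f$residuals^2) / sum((y - mean(y))^2)
  }
  phis <- 2 * pi * (seq_len(n_grid) - 1) / n_grid
  r2 <- vapply(phis, rsq_at, 0)
  best <- which.max(r2)
  phi <- phis[best]
  if (refine) {
    lo <- phis[best] - 2 * pi / n_grid
    hi <- phis[best] + 2 * pi / n_grid
    phi <- stats::optimize(rsq_at, c(lo, hi), maximum = TRUE,
                           tol = 1e-12)$maximum %% (2 * pi)
  }
  X <- cbind(1, cos(theta - phi), Xcov)
  co <- stats::lm.fit(X, y)$coefficients
  amp <- co[2]
  if (amp < 0) { amp <- -amp; phi <- (phi + pi) %% (2 * pi) }
  list(amplitude = unname(amp), acrophase_rad = phi)
}

## Nested-model F statistic from raw residual sums of squares.
rss_f_oracle <- function(data, outcome, covariates = character(),
                         date_col = "assess_date") {
  theta <- date_to_angle(data[[date_col]])
  y <- data[[outcome]]
  Xcov <- if (length(covariates)) as.matrix(data[covariates]) else NULL
  Xf <- cbind(1, cos(theta), sin(theta), Xcov)
  Xr <- cbind(1, Xcov)
  rss_f <- sum(stats::lm.fit(Xf, y)$residuals^2)
  rss_r <- sum(stats::lm.fit(Xr, y)$residuals^2)
  df2 <- length(y) - ncol(Xf)
  ((rss_r - rss_f) / 2) / (rss_f / df2)
}

## All-pairs point-to-interval scan (0-based half-open; distance 0 inside,
## else coordinate difference to the nearer edge base).
brute_link_oracle <- function(tss, tfbs, window_bp) {
  tfs <- sort(unique(tfbs$tf_name))
  out <- matrix(0L, nrow(tss), length(tfs),
                dimnames = list(tss$gene_id, tfs))
  for (i in seq_len(nrow(tss))) {
    for (j in seq_len(nrow(tfbs))) {
      if (tss$chrom[i] != tfbs$chrom[j]) next
      p <- tss$tss[i]; s <- tfbs$start[j]; e <- tfbs$end[j]
      d <- if (p >= s && p < e) 0 else if (p < s) s - p else p - (e - 1)
      if (d <= window_bp) out[i, tfbs$tf_name[j]] <- 1L
    }
  }
  out
}

## Spearman via explicit rank-then-Pearson.
rank_pearson_oracle <- function(x, y) stats::cor(rank(x), rank(y))

## Tiny cohort with an exact (noise-free) cosine signal.
noise_free_cohort <- function(n = 48L, amplitude = 0.3, acrophase_rad = 1.0,
                              level = 0) {
  dates <- as.Date("2015-01-01") + round(seq(0, 364, length.out = n))
  theta <- date_to_angle(dates)
  data.frame(assess_date = dates,
             outcome = level + amplitude * cos(theta - acrophase_rad))
}

## Small noisy cohort for calibration loops.
noisy_cohort <- function(n, amplitude = 0, acrophase_rad = 1,
                         beta_age = 0, sigma = 1) {
  dates <- as.Date("2015-01-01") + sample.int(365L, n, replace = TRUE) - 1L
  theta <- date_to_angle(dates)
  age <- stats::rnorm(n, 75, 7)
  data.frame(assess_date = dates, age_years = age,
             outcome = amplitude * cos(theta - acrophase_rad) +
               beta_age * (age - 75) + stats::rnorm(n, 0, sigma))
}
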
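test_that("amplitude_acrophase handles all quadrants and the origin", {
  expect_equal(amplitude_acrophase(0.1, 0), list(amplitude = 0.1, acrophase_rad = 0))
  expect_equal(amplitude_acrophase(0, -0.2),
               list(amplitude = 0.2, acrophase_rad = 3 * pi / 2))
  aa <- amplitude_acrophase(0.3, 0.4)
  expect_equal(aa$amplitude, 0.5)
  expect_equal(aa$acrophase_rad, atan2(0.4, 0.3), tolerance = 1e-12)
  expect_equal(amplitude_acrophase(0, 0), list(amplitude = 0, acrophase_rad = 0))
})

test_that("standardized_amplitude divides by a positive reference SD", {
  expect_equal(standardized_amplitude(0.063, 0.45), 0.14)
  expect_equal(standardized_amplitude(0, 0.45), 0)
  # affine invariance: rescaling outcome rescales both, quotient unchanged
  expect_equal(standardized_amplitude(0.063 * 7, 0.45 * 7), 0.14)
  expect_error(standardized_amplitude(0.1, 0), "positive")
  expect_error(standardized_amplitude(0.1, -1), "positive")
})

test_that("noise-free cosine outcome is identified exactly", {
  d <- noise_free_cohort(n = 60, amplitude = 0.3, acrophase_rad = 1.0)
  fit <- fit_cosinor(d, "outcome")
  expect_equal(fit$amplitude, 0.3, tolerance = 1e-8)
  expect_equal(fit$acrophase_rad, 1.0, tolerance = 1e-8)
  expect_lt(fit$p_rhythm, 1e-12)
  # nadir is exactly half a period from the acrophase
  expect_equal(circular_diff_days(fit$acrophase_date, fit$nadir_date),
               365.25 / 2, tolerance = 1e-9)
})

test_that("constant outcome gives zero amplitude and p near 1", {
  d <- noise_free_cohort(n = 40, amplitude = 0)
  d$outcome <- 1.7
  fit <- fit_cosinor(d, "outcome")
  expect_equal(fit$amplitude, 0, tolerance = 1e-12)
  expect_gt(fit$p_rhythm, 0.99)
})

test_that("fit_cosinor enforces its preconditions", {
  d <- noise_free_cohort(n = 8)
  expect_error(fit_cosinor(d, "outcome"), "fewer than 10")
  d <- noise_free_cohort(n = 30)
  d$dup <- d$outcome * 0 + 2  # constant column, collinear with intercept
  expect_error(fit_cosinor(d, "outcome", "dup"), "collinear")
  d2 <- noise_free_cohort(n = 30)
  d2$outcome <- NA_real_
  expect_error(fit_cosinor(d2, "outcome"))
  expect_error(fit_cosinor(noise_free_cohort(30), "nope"), "not found")
})

test_that("complete-case filtering is per-model and counted", {
  set.seed(4)
  d <- noisy_cohort(50)
  d$age_years[1:7] <- NA
  fit <- fit_cosinor(d, "outcome", "age_years")
  expect_equal(fit$n_used, 43L)
  expect_equal(fit$n_dropped, 7L)
  fit0 <- fit_cosinor(d, "outcome")
  expect_equal(fit0$n_used, 50L)
})

test_that("cohort fixed effect enters only with >1 level present", {
  set.seed(5)
  d <- noisy_cohort(60)
  d$cohort <- rep(c("A", "B"), 30)
  fit <- fit_cosinor(d, "outcome", cohort_col = "cohort")
  expect_true("cohortB" %in% names(fit$covariate_betas))
  d$cohort <- "A"
  fit1 <- fit_cosinor(d, "outcome", cohort_col = "cohort")
  expect_false(any(grepl("cohort", names(fit1$covariate_betas))))
})

test_that("quadrature fit matches the phase-grid-search oracle", {
  # noise-free with the true phase on a grid point: both exact
  phi_true <- 2 * pi * 900 / 3650
  d <- noise_free_cohort(n = 73, amplitude = 0.42, acrophase_rad = phi_true)
  fit <- fit_cosinor(d, "outcome")
  or <- grid_cosinor_oracle(d, "outcome", n_grid = 3650L)
  expect_equal(fit$amplitude, or$amplitude, tolerance = 1e-6)
  expect_equal(fit$acrophase_rad, or$acrophase_rad, tolerance = 1e-6)
  # noisy, with a covariate: compare against the refined continuous oracle
  set.seed(11)
  d2 <- noisy_cohort(150, amplitude = 0.5, acrophase_rad = 2.3,
                     beta_age = -0.03, sigma = 0.6)
  fit2 <- fit_cosinor(d2, "outcome", "age_years")
  or2 <- grid_cosinor_oracle(d2, "outcome", "age_years", n_grid = 3650L,
                             refine = TRUE)
  expect_equal(fit2$amplitude, or2$amplitude, tolerance = 1e-6)
  expect_equal(fit2$acrophase_rad, or2$acrophase_rad, tolerance = 1e-6)
})

test_that("F statistic equals the residual-sum-of-squares oracle", {
  set.seed(12)
  for (i in 1:5) {
    d <- noisy_cohort(80, amplitude = runif(1, 0, 0.5), beta_age = -0.02)
    fit <- fit_cosinor(d, "outcome", "age_years")
    expect_equal(fit$f_stat, rss_f_oracle(d, "outcome", "age_years"),
                 tolerance = 1e-10)
    rt <- rhythm_test(fit)
    expect_equal(rt$f_stat, fit$f_stat, tolerance = 1e-10)
    expect_identical(rt$df_num, 2L)
  }
})

test_that("rhythmicity p-values are null-calibrated (uniform under H0)", {
  set.seed(13)
  p <- replicate(1000, {
    d <- noisy_cohort(60)
    fit_cosinor(d, "outcome")$p_rhythm
  })
  # KS test against U(0,1) not rejected at alpha = 0.01
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
  # rejection rate at alpha = 0.05 within binomial error
  expect_lt(abs(mean(p < 0.05) - 0.05), 3 * sqrt(0.05 * 0.95 / 1000))
})

test_that("estimates are invariant to shifting dates by whole years", {
  set.seed(14)
  d <- noisy_cohort(80, amplitude = 0.4)
  d2 <- d
  # same month-day, different non-leap year: identical angular positions
  d2$assess_date <- as.Date(sub("^2015", "2013", as.character(d$assess_date)))
  f1 <- fit_cosinor(d, "outcome")
  f2 <- fit_cosinor(d2, "outcome")
  expect_equal(f1$amplitude, f2$amplitude, tolerance = 1e-12)
  expect_equal(f1$acrophase_rad, f2$acrophase_rad, tolerance = 1e-12)
})

test_that("age_equivalent converts the seasonal swing into years of age", {
  set.seed(15)
  d <- noisy_cohort(500, amplitude = 0.3, beta_age = -0.03, sigma = 0.01)
  fit <- fit_cosinor(d, "outcome", "age_years")
  ae <- age_equivalent(fit)
  expect_equal(ae$years, 2 * fit$amplitude / abs(fit$covariate_betas[["age_years"]]))
  # doubling the amplitude doubles the years
  fit2 <- fit
  fit2$amplitude <- 2 * fit$amplitude
  expect_equal(age_equivalent(fit2)$years, 2 * ae$years)
  # zero amplitude -> zero years
  fit0 <- fit; fit0$amplitude <- 0
  expect_equal(age_equivalent(fit0)$years, 0)
  # degenerate age slope is flagged, not returned
  fitd <- fit; fitd$covariate_betas[["age_years"]] <- 1e-12
  expect_error(age_equivalent(fitd), "undefined")
  expect_error(age_equivalent(fit_cosinor(d, "outcome")), "no 'age_years'")
})

test_that("preset arithmetic reproduces the published age-equivalence", {
  # amplitude 0.063 units with age slope -0.02625/yr -> 4.8 years
  expect_equal(2 * 0.063 / 0.02625, 4.8, tolerance = 1e-12)
})

test_that("bootstrap is deterministic and degenerates on noise-free data", {
  d <- noise_free_cohort(n = 40, amplitude = 0.3, acrophase_rad = 1)
  fit <- fit_cosinor(d, "outcome")
  b1 <- bootstrap_ci(fit, B = 200, seed = 42)
  b2 <- bootstrap_ci(fit, B = 200, seed = 42)
  expect_identical(b1$amplitude_ci, b2$amplitude_ci)
  expect_equal(b1$amplitude_ci, c(0.3, 0.3), tolerance = 1e-9)
  expect_error(bootstrap_ci(fit, B = 50), ">= 200")
})

test_that("bootstrap intervals cover the generating amplitude", {
  set.seed(16)
  hits <- replicate(60, {
    d <- noisy_cohort(150, amplitude = 0.5, sigma = 0.5)
    fit <- bootstrap_ci(fit_cosinor(d, "outcome"), B = 200)
    fit$amplitude_ci[1] <= 0.5 && 0.5 <= fit$amplitude_ci[2]
  })
  # nominal 95%, allow 4 MC standard errors around it
  expect_gt(mean(hits), 0.95 - 4 * sqrt(0.95 * 0.05 / 60))
})

test_that("report row carries the headline quantities", {
  d <- noise_free_cohort(30)
  row <- fit_report_row(fit_cosinor(d, "outcome"))
  expect_identical(nrow(row), 1L)
  expect_true(all(c("amplitude", "amplitude_std", "acrophase_date",
                    "p_rhythm", "n_used") %in% names(row)))
})
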
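## Small block-structured expression fixture built in code.
tiny_expression <- function(n_genes = 120L, n_samples = 60L, n_modules = 6L,
                            planted = NULL, r = 0.4, seed = 1L) {
  set.seed(seed)
  genes <- sprintf("g%03d", seq_len(n_genes))
  size <- n_genes %/% n_modules
  defs <- data.frame(gene = genes,
                     module = rep(sprintf("m%02d", seq_len(n_modules)),
                                  each = size, length.out = n_genes))
  dates <- as.Date("2015-01-01") + sample.int(365L, n_samples, TRUE) - 1L
  theta <- date_to_angle(dates)
  meta <- data.frame(sample_id = sprintf("s%03d", seq_len(n_samples)),
                     death_date = dates,
                     age_death = stats::rnorm(n_samples, 85, 6))
  fac <- matrix(stats::rnorm(n_samples * n_modules), n_samples, n_modules,
                dimnames = list(NULL, unique(defs$module)))
  if (!is.null(planted)) {
    for (m in names(planted)) {
      a <- planted[[m]]$amp
      acro <- if (is.null(planted[[m]]$acro)) 1 else planted[[m]]$acro
      phi <- 2 * pi * (acro - 1) / 365.25
      fac[, m] <- a * cos(theta - phi) +
        stats::rnorm(n_samples, 0, sqrt(max(1 - a^2 / 2, 0.05)))
    }
  }
  mat <- sqrt(r) * t(fac[, defs$module]) +
    matrix(stats::rnorm(n_genes * n_samples, 0, sqrt(1 - r)), n_genes)
  dimnames(mat) <- list(genes, meta$sample_id)
  cogload <- vapply(colnames(fac), function(m)
    if (!is.null(planted[[m]]$cog)) planted[[m]]$cog else 0, 0)
  meta$cognition <- as.vector(fac %*% cogload) + stats::rnorm(n_samples, 0, 0.6)
  list(mat = mat, defs = defs, meta = meta, factors = fac)
}

test_that("normalize_expression z-scores rows and drops constant genes", {
  m <- rbind(a = c(1, 2, 3), b = c(5, 5, 5), d = c(0, 10, 20))
  colnames(m) <- paste0("s", 1:3)
  expect_warning(z <- normalize_expression(m), "zero-variance")
  expect_identical(rownames(z), c("a", "d"))
  expect_equal(z["a", ], c(-1, 0, 1) / stats::sd(c(1, 2, 3)) * 1,
               ignore_attr = TRUE)
  expect_lt(max(abs(rowMeans(z))), 1e-12)
  expect_equal(unname(apply(z, 1, stats::sd)), c(1, 1))
  expect_error(normalize_expression(rbind(c(1, NA))), "rownames|missing")
})

test_that("summarize_modules averages member z-rows", {
  fx <- tiny_expression(seed = 2)
  z <- normalize_expression(fx$mat)
  sc <- summarize_modules(z, fx$defs)
  # single-gene module equals that gene's z-row
  one <- summarize_modules(z, data.frame(gene = "g001", module = "solo"))
  expect_equal(one["solo", ], z["g001", ])
  # two perfectly anticorrelated genes average to ~0
  z2 <- rbind(p = z["g001", ], q = -z["g001", ])
  anti <- summarize_modules(z2, data.frame(gene = c("p", "q"),
                                           module = c("x", "x")))
  expect_lt(max(abs(anti)), 1e-12)
  # linear-algebra oracle: normalized membership-indicator matrix times z
  ml <- split(fx$defs$gene, fx$defs$module)
  M <- t(vapply(ml, function(g) as.numeric(rownames(z) %in% g) / length(g),
                numeric(nrow(z))))
  expect_equal(unname(sc[names(ml), ]), unname(M %*% z), tolerance = 1e-12)
  # modules with insufficient overlap are skipped with a warning
  defs_bad <- rbind(fx$defs,
                    data.frame(gene = sprintf("missing%d", 1:10),
                               module = "mZZ"))
  expect_warning(sc2 <- summarize_modules(z, defs_bad), "mZZ")
  expect_false("mZZ" %in% rownames(sc2))
})

test_that("summarize_modules is linear over disjoint unions", {
  fx <- tiny_expression(seed = 3)
  z <- normalize_expression(fx$mat)
  defs <- data.frame(gene = c("g001", "g002", "g003", "g004", "g005"),
                     module = c("a", "a", "b", "b", "b"))
  sc <- summarize_modules(z, defs)
  un <- summarize_modules(z, data.frame(gene = defs$gene, module = "u"))
  expect_equal(un["u", ], (2 * sc["a", ] + 3 * sc["b", ]) / 5,
               tolerance = 1e-12)
})

test_that("rhythm scan recovers planted module rhythms", {
  fx <- tiny_expression(
    n_samples = 150,
    planted = list(m01 = list(amp = 0.8, acro = 266)), seed = 4)
  z <- normalize_expression(fx$mat)
  sc <- summarize_modules(z, fx$defs)
  rs <- module_rhythm_scan(sc, fx$meta, covariates = "age_death")
  expect_lt(rs$p_raw[rs$module == "m01"], 1e-4)
  expect_lt(circular_diff_days(rs$acrophase_date[rs$module == "m01"], 266), 30)
  # non-rhythmic modules keep raw p away from systematic smallness
  expect_gt(min(rs$p_raw[rs$module != "m01"]), 1e-4)
})

test_that("cognition association equals the simple-regression oracle", {
  fx <- tiny_expression(planted = list(m02 = list(amp = 0, cog = 0.9)),
                        seed = 5)
  z <- normalize_expression(fx$mat)
  sc <- summarize_modules(z, fx$defs)
  cs <- cognition_association_scan(sc, fx$meta, "cognition")
  for (m in c("m01", "m02")) {
    o <- stats::lm(fx$meta$cognition ~ sc[m, ])
    expect_equal(cs$beta[cs$module == m], unname(coef(o)[2]),
                 tolerance = 1e-10)
  }
  expect_gt(cs$beta[cs$module == "m02"], 0)
  expect_lt(cs$p_raw[cs$module == "m02"], 0.01)
})

test_that("permutation adjustment is monotone, deterministic, label-invariant", {
  fx <- tiny_expression(n_samples = 80,
                        planted = list(m03 = list(amp = 0.9, cog = 0.8)),
                        seed = 6)
  z <- normalize_expression(fx$mat)
  a1 <- permutation_adjust(z, fx$defs, fx$meta, "rhythm",
                           covariates = "age_death", n_perm = 200, seed = 9)
  a2 <- permutation_adjust(z, fx$defs, fx$meta, "rhythm",
                           covariates = "age_death", n_perm = 200, seed = 9)
  expect_identical(a1, a2)
  expect_true(all(a1$p_adj >= a1$p_perm))
  expect_true(all(a1$p_adj > 0 & a1$p_adj <= 1))
  # shuffling the order of module-definition rows changes nothing
  a3 <- permutation_adjust(z, fx$defs[sample(nrow(fx$defs)), ], fx$meta,
                           "rhythm", covariates = "age_death",
                           n_perm = 200, seed = 9)
  expect_identical(a1, a3)
  # statistic = "both" reproduces the rhythm family from the same stream
  ab <- permutation_adjust(z, fx$defs, fx$meta, "both",
                           covariates = "age_death",
                           cognition_col = "cognition",
                           n_perm = 200, seed = 9)
  expect_equal(ab$p_adj_rhythm, a1$p_adj)
  expect_error(permutation_adjust(z, fx$defs, fx$meta, "cognition",
                                  n_perm = 200), "cognition_col")
  expect_error(permutation_adjust(z, fx$defs, fx$meta, "rhythm", n_perm = 50),
               ">= 100")
})

test_that("observed permutation statistics match the per-module fits", {
  fx <- tiny_expression(n_samples = 70,
                        planted = list(m01 = list(amp = 0.7, cog = 0.5)),
                        seed = 7)
  z <- normalize_expression(fx$mat)
  sc <- summarize_modules(z, fx$defs)
  ad <- permutation_adjust(z, fx$defs, fx$meta, "both",
                           covariates = "age_death",
                           cognition_col = "cognition",
                           cognition_covariates = "age_death",
                           n_perm = 100, seed = 3)
  rs <- module_rhythm_scan(sc, fx$meta, "age_death")
  cs <- cognition_association_scan(sc, fx$meta, "cognition", "age_death")
  expect_equal(ad$stat_rhythm[match(rs$module, ad$module)],
               rs$f_stat, tolerance = 1e-9)
  expect_equal(ad$stat_cognition[match(cs$module, ad$module)],
               abs(cs$t_stat), tolerance = 1e-9)
})

test_that("family-wise error is controlled under the null", {
  set.seed(41)
  false_families <- replicate(20, {
    fx <- tiny_expression(n_genes = 200, n_samples = 60, n_modules = 10,
                          seed = sample.int(1e6, 1))
    z <- normalize_expression(fx$mat)
    ad <- permutation_adjust(z, fx$defs, fx$meta, "rhythm",
                             n_perm = 1000, seed = sample.int(1e6, 1))
    any(ad$p_adj < 0.05)
  })
  # expected ~1 false family in 20 runs at FWER 0.05
  expect_lte(sum(false_families), 3)
})

test_that("phase concordance classifies against acrophase and nadir", {
  expect_identical(as.character(phase_concordance(266, 266)), "in_phase")
  expect_identical(as.character(phase_concordance(266 + 182.625, 266)),
                   "anti_phase")
  expect_identical(as.character(phase_concordance(266 + 61, 266, 60.875)),
                   "neither")
  expect_identical(as.character(phase_concordance(266 + 60.875, 266, 60.875)),
                   "in_phase")  # strict <= boundary
  # wraps across the year boundary
  expect_identical(as.character(phase_concordance(5, 360)), "in_phase")
})

test_that("selection report is the conjunction of the three criteria", {
  fx <- tiny_expression(
    n_samples = 120,
    planted = list(m01 = list(amp = 0.9, acro = 266, cog = 0.9),
                   m02 = list(amp = 0.9, acro = 100)),  # rhythmic, wrong phase
    seed = 8)
  res <- run_module_selection(
    fx$mat, fx$defs, fx$meta, covariates = "age_death",
    cognition_col = "cognition", cognition_acrophase_date = 266,
    n_perm = 400, seed = 12)
  sel <- res$selection
  expect_true(sel$selected_flag[sel$module == "m01"])
  expect_false(sel$selected_flag[sel$module == "m02"])
  expect_identical(sel$selected_flag,
                   sel$p_rhythm_adj < 0.05 & sel$in_phase_flag &
                     sel$p_cog_adj < 0.05)
})

test_that("Spearman grid matches the rank-Pearson oracle", {
  fx <- tiny_expression(seed = 9)
  z <- normalize_expression(fx$mat)
  sc <- summarize_modules(z, fx$defs)
  ph <- data.frame(sample_id = fx$meta$sample_id,
                   pheno1 = fx$meta$cognition,
                   pheno2 = exp(fx$meta$cognition),  # monotone transform
                   flat = 1)
  g <- phenotype_correlation_grid(sc, ph)
  for (m in rownames(sc)) {
    expect_equal(g$rho[g$module == m & g$phenotype == "pheno1"],
                 rank_pearson_oracle(sc[m, ], ph$pheno1), tolerance = 1e-10)
  }
  # rank invariance under monotone transforms
  expect_equal(g$rho[g$phenotype == "pheno1"], g$rho[g$phenotype == "pheno2"],
               tolerance = 1e-12)
  # a phenotype equal to a module's score correlates perfectly
  ph2 <- data.frame(sample_id = fx$meta$sample_id, self = sc["m01", ])
  g2 <- phenotype_correlation_grid(sc, ph2)
  expect_equal(g2$rho[g2$module == "m01"], 1.0, tolerance = 1e-12)
  # constant phenotype is undefined, not an error
  expect_true(all(is.na(g$rho[g$phenotype == "flat"])))
  expect_true(all(g$p_bonf >= g$p, na.rm = TRUE))
})
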
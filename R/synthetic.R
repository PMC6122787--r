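## Seeded synthetic-data generators for every analysis stage, with ground
## truth emitted alongside.  Presets encode the published cohort summaries
## (sample sizes, means/SDs, amplitudes, acrophases, odds ratios) so that
## parameter-recovery tests have a known stated world.

.rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  lo <- stats::pnorm((lower - mean) / sd)
  hi <- stats::pnorm((upper - mean) / sd)
  mean + sd * stats::qnorm(stats::runif(n, lo, hi))
}

.runif_dates <- function(n, years = 2012:2016) {
  yr <- sample(years, n, replace = TRUE)
  as.Date(paste0(yr, "-01-01")) + sample.int(365L, n, replace = TRUE) - 1L
}

#' Built-in synthetic presets
#'
#' Returns the configuration list for one of the named presets:
#' \describe{
#'   \item{combined}{community cohorts pooled (n = 2,761): composite
#'     cognition with a 0.14-SD rhythm peaking day 266, age slope set so the
#'     seasonal swing equals 4.8 years of aging, and an MCI/dementia model
#'     with prevalence 29.5% and winter/spring OR 1.31.}
#'   \item{mars}{single minority cohort (n = 527), weaker rhythm.}
#'   \item{sds}{memory-clinic DRS scores (n = 271), amplitude 0.50 SD,
#'     acrophase Nov 16 (day 320).}
#'   \item{cnc}{CSF biomarkers (n = 321, 176 AD): Aβ42 rhythmic
#'     (0.30 SD pooled, acrophase day 172, halved in AD), Aβ40/tau/p-tau
#'     non-rhythmic, AD offsets in level.}
#'   \item{expression}{5,000 genes x 507 samples, 47 modules; four planted
#'     rhythmic cognition-associated modules with the published sizes and
#'     amplitudes (m6 328/0.44, m13 353/0.46, m109 390/0.43,
#'     m122 370/0.46), two in phase and two antiphase to cognition.}
#'   \item{tfbs}{synthetic chromosome with 161 TFs, baseline target
#'     probability 0.08, and the five planted TF-module enrichments
#'     (BCL11A/EGR1/MEF2C/THAP1 -> m109, CTCF -> m13) at log-OR 1.0.}
#' }
#'
#' @param name preset name.
#' @return named configuration list; fields may be overridden before being
#'   passed to a generator.
#' @export
seasonal_preset <- function(name = c("combined", "mars", "sds", "cnc",
                                     "expression", "tfbs")) {
  name <- match.arg(name)
  switch(name,
    combined = list(
      kind = "cohort", n = 2761L,
      cohorts = c(ROSMAP = 2234 / 2761, MARS = 527 / 2761),
      cohort_offsets = c(ROSMAP = 0, MARS = -0.07),
      age_mean = 76, age_sd = 7, age_min = 60,
      p_female = 0.754, edu_mean = 16, edu_sd = 3,
      outcome_mean = 0.26, sd_total = 0.45,
      amplitude = 0.14 * 0.45, acrophase_day = 266,
      beta_age = -0.02625, beta_sex = 0.05, beta_edu = 0.02,
      diagnosis = list(prevalence = 813 / 2761, season_log_or = log(1.31),
                       mechanism = "categorical",
                       beta_age = 0.05, beta_sex = -0.2, beta_edu = -0.08,
                       cohort_offsets = c(ROSMAP = 0, MARS = 0.2)),
      confounders = TRUE, confounder_seasonal = FALSE,
      group = NULL),
    mars = list(
      kind = "cohort", n = 527L,
      cohorts = c(MARS = 1), cohort_offsets = c(MARS = 0),
      age_mean = 72, age_sd = 6, age_min = 60,
      p_female = 0.793, edu_mean = 14, edu_sd = 3,
      outcome_mean = 0.19, sd_total = 0.47,
      amplitude = 0.105 * 0.47, acrophase_day = 266,
      beta_age = -0.025, beta_sex = 0.05, beta_edu = 0.02,
      diagnosis = NULL, confounders = TRUE, confounder_seasonal = FALSE,
      group = NULL),
    sds = list(
      kind = "cohort", n = 271L,
      cohorts = c(SDS = 1), cohort_offsets = c(SDS = 0),
      age_mean = 72, age_sd = 9, age_min = 40,
      p_female = 0.487, edu_mean = 13, edu_sd = 3,
      outcome_mean = 115, sd_total = 17,
      amplitude = 0.50 * 17, acrophase_day = 320,
      beta_age = -0.3, beta_sex = 2, beta_edu = 0.3,
      diagnosis = NULL, confounders = FALSE, confounder_seasonal = FALSE,
      group = NULL),
    cnc = list(
      kind = "csf", n = 321L, n_ad = 176L,
      age_mean = 68.6, age_sd = 9, age_min = 40, p_female = 0.567,
      analytes = list(
        abeta42 = list(mean = 900, ad_offset = -266, sd_total = 280,
                       amplitude_std_pooled = 0.30, acrophase_day = 172,
                       ad_amp_factor = 0.5, beta_age = -2),
        abeta40 = list(mean = 11300, ad_offset = 1000, sd_total = 4856,
                       amplitude_std_pooled = 0, acrophase_day = 172,
                       ad_amp_factor = 1, beta_age = -20),
        tau = list(mean = 350, ad_offset = 220, sd_total = 318,
                   amplitude_std_pooled = 0, acrophase_day = 172,
                   ad_amp_factor = 1, beta_age = 3),
        ptau = list(mean = 55, ad_offset = 30, sd_total = 40,
                    amplitude_std_pooled = 0, acrophase_day = 172,
                    ad_amp_factor = 1, beta_age = 0.5))),
    expression = list(
      kind = "expression", n_genes = 5000L, n_samples = 507L,
      n_modules = 47L, size_range = c(20L, 80L),
      within_module_r = 0.3,
      planted = data.frame(
        module = c("m6", "m13", "m109", "m122"),
        size = c(328L, 353L, 390L, 370L),
        amplitude_std = c(0.44, 0.46, 0.43, 0.46),
        acrophase_day = c(83.4, 266, 83.4, 266),
        cognition_loading = c(-0.3, 0.3, -0.3, 0.3),
        stringsAsFactors = FALSE),
      cognition_acrophase_day = 266,
      batch_levels = 4L, batch_sd = 0.2,
      age_mean = 88, age_sd = 6, age_min = 65, p_female = 0.62,
      edu_mean = 16, edu_sd = 3),
    tfbs = list(
      kind = "tfbs", n_tf = 161L, p0 = 0.08, window_bp = 2000L,
      spacing_bp = 10000L, gene_len = 1000L, site_len = 150L,
      chrom = "chrS",
      planted = data.frame(
        tf = c("BCL11A", "EGR1", "MEF2C", "THAP1", "CTCF"),
        module = c("m109", "m109", "m109", "m109", "m13"),
        log_or = rep(1.0, 5), stringsAsFactors = FALSE))
  )
}

## Sample the module-definition table used by the expression and tfbs
## generators: planted modules keep their exact sizes; the remaining
## modules get sizes from size_range; leftover genes stay unassigned.
.sample_module_defs <- function(cfg) {
  planted <- cfg$planted[cfg$planted$size > 0, , drop = FALSE]
  n_bg <- cfg$n_modules - nrow(planted)
  bg_sizes <- sample(seq(cfg$size_range[1], cfg$size_range[2]), n_bg,
                     replace = TRUE)
  sizes <- c(stats::setNames(planted$size, planted$module),
             stats::setNames(bg_sizes, sprintf("b%02d", seq_len(n_bg))))
  if (sum(sizes) > cfg$n_genes)
    stop("module sizes exceed the gene universe (",
         sum(sizes), " > ", cfg$n_genes, ")")
  genes <- sprintf("g%05d", seq_len(cfg$n_genes))
  assigned <- sample(genes, sum(sizes))
  data.frame(gene = assigned,
             module = rep(names(sizes), times = sizes),
             stringsAsFactors = FALSE)
}

#' Generate a synthetic participant cohort with a seasonal cognition rhythm
#'
#' Draws assessment dates uniformly over the calendar year, demographic
#' covariates from the preset distributions, and the continuous outcome as
#' \deqn{y = \mu + \beta_{age}(age - \bar a) + \beta_{sex} sex +
#'  \beta_{edu}(edu - \bar e) + c_{cohort} + A\cos(\theta - \phi) +
#'  \epsilon,}
#' with the residual SD set so the realized total SD matches `sd_total`
#' (error if infeasible).  A binary MCI/dementia diagnosis is drawn from a
#' logistic model with a winter/spring log-odds excess (intercept
#' calibrated so the realized-covariate expected prevalence matches the
#' preset), an optional binary group modulates level and amplitude, and
#' independent confounder columns (test hour, depression, sleep, activity,
#' TSH) are attached when enabled.
#'
#' @param config preset list from [seasonal_preset()] (possibly modified).
#' @param seed integer seed; output is a pure function of (config, seed).
#' @return list with `data` (the cohort table) and `truth` (every
#'   generating parameter realized).
#' @export
generate_cohort <- function(config = seasonal_preset("combined"), seed = 1L) {
  stopifnot(config$kind == "cohort")
  set.seed(seed)
  n <- config$n
  cohort <- sample(names(config$cohorts), n, replace = TRUE,
                   prob = config$cohorts)
  assess_date <- .runif_dates(n)
  theta <- date_to_angle(assess_date)
  age <- .rtruncnorm(n, config$age_mean, config$age_sd, config$age_min)
  sex <- stats::rbinom(n, 1L, config$p_female)
  edu <- round(.rtruncnorm(n, config$edu_mean, config$edu_sd, 6, 25))
  phi <- 2 * pi * (config$acrophase_day - 1) / 365.25

  amp <- rep(config$amplitude, n)
  group <- NULL
  lvl <- 0
  if (!is.null(config$group)) {
    group <- stats::rbinom(n, 1L, config$group$fraction)
    amp <- ifelse(group == 1L, amp * config$group$amp_factor, amp)
    lvl <- config$group$level_offset * group
  }
  fixed <- config$outcome_mean +
    config$beta_age * (age - config$age_mean) +
    config$beta_sex * sex +
    config$beta_edu * (edu - config$edu_mean) +
    config$cohort_offsets[cohort] +
    lvl + amp * cos(theta - phi)
  resid_var <- config$sd_total^2 - stats::var(fixed)
  if (resid_var <= 0)
    stop("generate_cohort: infeasible variance decomposition (systematic ",
         "variance exceeds sd_total^2)")
  outcome <- as.numeric(fixed + stats::rnorm(n, 0, sqrt(resid_var)))

  d <- data.frame(
    participant_id = sprintf("P%05d", seq_len(n)),
    assess_date = assess_date, outcome = outcome,
    age_years = age, sex = sex, education_years = edu,
    cohort = cohort, stringsAsFactors = FALSE)
  if (!is.null(group)) d$path_ad <- group

  dx_b0 <- NA_real_
  if (!is.null(config$diagnosis)) {
    dx <- config$diagnosis
    lin <- dx$beta_age * (age - config$age_mean) + dx$beta_sex * sex +
      dx$beta_edu * (edu - config$edu_mean) + dx$cohort_offsets[cohort]
    if (identical(dx$mechanism, "cosine")) {
      lin <- lin + dx$season_log_or * cos(theta - phi + pi)
    } else {
      ws <- as.integer(categorical_season(assess_date) == "winter_spring")
      lin <- lin + dx$season_log_or * ws
    }
    dx_b0 <- stats::uniroot(function(b0)
      mean(stats::plogis(b0 + lin)) - dx$prevalence, c(-30, 30))$root
    case <- stats::rbinom(n, 1L, stats::plogis(dx_b0 + lin))
    ## split the positive class into MCI and dementia ~ the published 457:356
    split_mci <- stats::rbinom(n, 1L, 457 / 813)
    d$mci_dementia <- case
    d$diagnosis <- ifelse(case == 0L, "NCI",
                          ifelse(split_mci == 1L, "MCI", "dementia"))
  }
  if (isTRUE(config$confounders)) {
    seas <- if (isTRUE(config$confounder_seasonal)) cos(theta - phi + pi) else 0
    d$test_hour <- factor(sample(8:16, n, replace = TRUE))
    d$depression <- stats::rpois(n, pmax(1.2 + 0.4 * seas, 0.05))
    d$sleep_hours <- stats::rnorm(n, 7 + 0.3 * seas, 1.2)
    d$activity_hours <- stats::rgamma(n, shape = 2, scale = 1.7)
    d$tsh <- stats::rlnorm(n, 0.7, 0.4)
  }
  truth <- list(
    preset_n = n, seed = seed,
    outcome_mean = config$outcome_mean, sd_total = config$sd_total,
    amplitude = config$amplitude,
    amplitude_std = config$amplitude / config$sd_total,
    acrophase_day = config$acrophase_day,
    beta_age = config$beta_age, beta_sex = config$beta_sex,
    beta_edu = config$beta_edu,
    cohort_offsets = as.list(config$cohort_offsets),
    resid_sd = sqrt(resid_var),
    age_equiv_years = 2 * config$amplitude / abs(config$beta_age),
    group = config$group,
    diagnosis = if (is.null(config$diagnosis)) NULL else
      c(config$diagnosis[c("prevalence", "mechanism")],
        list(season_log_or = config$diagnosis$season_log_or,
             season_or = exp(config$diagnosis$season_log_or),
             intercept = dx_b0)))
  list(data = d, truth = truth)
}

#' Generate synthetic CSF biomarker data
#'
#' One lumbar puncture per patient: dates uniform over the year, an AD /
#' non-AD diagnosis with the preset case count, and four analytes with
#' group-dependent level and rhythm.  The rhythmic analyte's per-group
#' amplitudes are set so the size-weighted pooled amplitude equals the
#' preset pooled standardized amplitude (the AD group attenuated by
#' `ad_amp_factor`); negative concentrations are truncated at zero and the
#' truncation count recorded in the truth.
#'
#' @inheritParams generate_cohort
#' @return list with `data` and `truth`.
#' @export
generate_csf <- function(config = seasonal_preset("cnc"), seed = 1L) {
  stopifnot(config$kind == "csf")
  set.seed(seed)
  n <- config$n
  ad <- as.integer(sample(rep(c(1L, 0L), c(config$n_ad, n - config$n_ad))))
  lp_date <- .runif_dates(n)
  theta <- date_to_angle(lp_date)
  age <- .rtruncnorm(n, config$age_mean, config$age_sd, config$age_min)
  sex <- stats::rbinom(n, 1L, config$p_female)
  d <- data.frame(participant_id = sprintf("C%04d", seq_len(n)),
                  lp_date = lp_date, age_years = age, sex = sex,
                  diagnosis = ifelse(ad == 1L, "AD", "nonAD"),
                  ad = ad, stringsAsFactors = FALSE)
  truth <- list(seed = seed, n = n, n_ad = config$n_ad, analytes = list())
  w_ad <- config$n_ad / n
  for (nm in names(config$analytes)) {
    a <- config$analytes[[nm]]
    phi <- 2 * pi * (a$acrophase_day - 1) / 365.25
    amp_pooled <- a$amplitude_std_pooled * a$sd_total
    amp_non <- amp_pooled / ((1 - w_ad) + a$ad_amp_factor * w_ad)
    amp_i <- ifelse(ad == 1L, amp_non * a$ad_amp_factor, amp_non)
    fixed <- a$mean + a$ad_offset * ad +
      a$beta_age * (age - config$age_mean) + amp_i * cos(theta - phi)
    resid_var <- a$sd_total^2 - stats::var(fixed)
    if (resid_var <= 0)
      stop("generate_csf: infeasible variance decomposition for ", nm)
    val <- fixed + stats::rnorm(n, 0, sqrt(resid_var))
    n_trunc <- sum(val < 0)
    d[[nm]] <- pmax(val, 0)
    truth$analytes[[nm]] <- list(
      mean_nonad = a$mean, ad_offset = a$ad_offset, sd_total = a$sd_total,
      amplitude_pooled = amp_pooled,
      amplitude_std_pooled = a$amplitude_std_pooled,
      amplitude_nonad = amp_non,
      amplitude_ad = amp_non * a$ad_amp_factor,
      acrophase_day = a$acrophase_day, beta_age = a$beta_age,
      resid_sd = sqrt(resid_var), n_truncated = n_trunc)
  }
  list(data = d, truth = truth)
}

#' Generate a synthetic expression matrix with planted rhythmic modules
#'
#' Block-correlated genes x samples matrix: each module has a latent
#' per-sample factor (unit variance) shared by its genes with loading
#' \eqn{\sqrt{r}}; planted modules' factors carry a seasonal cosine of the
#' death date at the preset standardized amplitude and load on a latent
#' cognition variable with the preset sign (in-phase positive, antiphase
#' negative).  Sample metadata (death date/hour, age at death, sex,
#' education, PMI, RIN, batch) is generated alongside; batch adds small
#' gene-level offsets.  Unassigned genes are pure noise.
#'
#' @inheritParams generate_cohort
#' @return list with `mat` (genes x samples), `modules` (gene/module
#'   table), `meta` (sample metadata incl. `cognition`), and `truth`.
#' @export
generate_expression <- function(config = seasonal_preset("expression"),
                                seed = 1L) {
  stopifnot(config$kind == "expression")
  set.seed(seed)
  defs <- .sample_module_defs(config)
  n_s <- config$n_samples
  genes <- sprintf("g%05d", seq_len(config$n_genes))
  death_date <- .runif_dates(n_s)
  theta <- date_to_angle(death_date)
  meta <- data.frame(
    sample_id = sprintf("S%04d", seq_len(n_s)),
    death_date = death_date,
    death_hour = factor(sample(0:23, n_s, replace = TRUE)),
    age_death = .rtruncnorm(n_s, config$age_mean, config$age_sd,
                            config$age_min),
    sex = stats::rbinom(n_s, 1L, config$p_female),
    education_years = round(.rtruncnorm(n_s, config$edu_mean, config$edu_sd,
                                        6, 25)),
    pmi_hours = stats::rgamma(n_s, shape = 4, scale = 2),
    rin = .rtruncnorm(n_s, 7, 1, 5, 10),
    batch = factor(sample(seq_len(config$batch_levels), n_s, replace = TRUE)),
    stringsAsFactors = FALSE)

  mods <- unique(defs$module)
  planted <- config$planted
  factors <- matrix(0, nrow = n_s, ncol = length(mods),
                    dimnames = list(NULL, mods))
  for (m in mods) {
    i <- match(m, planted$module)
    if (!is.na(i)) {
      a <- planted$amplitude_std[i]
      phi <- 2 * pi * (planted$acrophase_day[i] - 1) / 365.25
      factors[, m] <- a * cos(theta - phi) +
        stats::rnorm(n_s, 0, sqrt(1 - a^2 / 2))
    } else {
      factors[, m] <- stats::rnorm(n_s)
    }
  }
  r <- config$within_module_r
  mat <- matrix(stats::rnorm(config$n_genes * n_s, 0, sqrt(1 - r)),
                nrow = config$n_genes, dimnames = list(genes, meta$sample_id))
  idx <- match(defs$gene, genes)
  mat[idx, ] <- sqrt(r) * t(factors[, defs$module, drop = FALSE]) +
    matrix(stats::rnorm(length(idx) * n_s, 0, sqrt(1 - r)),
           nrow = length(idx))
  ## gene baseline means and small gene-by-batch offsets
  mat <- mat + stats::rnorm(config$n_genes, 5, 2)
  boff <- matrix(stats::rnorm(config$n_genes * config$batch_levels, 0,
                              config$batch_sd), ncol = config$batch_levels)
  mat <- mat + boff[, as.integer(meta$batch)]

  lam <- planted$cognition_loading
  cog_fixed <- as.vector(factors[, planted$module, drop = FALSE] %*% lam) -
    0.02 * (meta$age_death - config$age_mean) + 0.05 * meta$sex +
    0.02 * (meta$education_years - config$edu_mean)
  cog_resid <- 1 - stats::var(cog_fixed)
  if (cog_resid <= 0)
    stop("generate_expression: infeasible cognition variance decomposition")
  meta$cognition <- as.numeric(cog_fixed + stats::rnorm(n_s, 0, sqrt(cog_resid)))

  truth <- list(
    seed = seed, n_genes = config$n_genes, n_samples = n_s,
    n_modules = length(mods), within_module_r = r,
    planted = planted,
    cognition_acrophase_day = config$cognition_acrophase_day,
    module_sizes = as.list(table(defs$module)))
  list(mat = mat, modules = defs, meta = meta, truth = truth)
}

#' Generate synthetic gene and TFBS interval tracks with planted enrichment
#'
#' Tiles genes along one synthetic chromosome (alternating strands, spacing
#' wide enough that windows never overlap neighboring genes), samples the
#' gene x TF target indicator matrix from a logistic model — baseline
#' probability `p0`, elevated by `log_or` for planted (TF, module) pairs —
#' and then *constructs* binding-site intervals so that [link_tfbs()]
#' reproduces the sampled indicators exactly: a site is placed within the
#' window of each targeted gene's TSS and nowhere near untargeted TSSs.
#'
#' @inheritParams generate_cohort
#' @param modules optional gene/module definition table (e.g. from
#'   [generate_expression()]); by default a fresh one is sampled with the
#'   expression preset's module scheme.
#' @return list with `genes` (BED-style data frame with strand), `tfbs`
#'   (BED-style data frame), `targets` (the sampled truth indicator
#'   matrix), `modules`, and `truth`.
#' @export
generate_tfbs <- function(config = seasonal_preset("tfbs"), seed = 1L,
                          modules = NULL) {
  stopifnot(config$kind == "tfbs")
  set.seed(seed)
  if (is.null(modules)) {
    ecfg <- seasonal_preset("expression")
    modules <- .sample_module_defs(ecfg)
    genes_all <- sprintf("g%05d", seq_len(ecfg$n_genes))
  } else {
    genes_all <- sort(unique(modules$gene))
  }
  n_g <- length(genes_all)
  n_extra <- config$n_tf - length(unique(config$planted$tf))
  tf_names <- c(unique(config$planted$tf), sprintf("TF%03d", seq_len(n_extra)))

  spacing <- config$spacing_bp
  tss_pos <- spacing * seq_len(n_g)
  strand <- rep(c("+", "-"), length.out = n_g)
  glen <- config$gene_len
  gstart <- ifelse(strand == "+", tss_pos, tss_pos - glen + 1L)
  gend <- gstart + glen
  genes <- data.frame(gene_id = genes_all, chrom = config$chrom,
                      start = gstart, end = gend, strand = strand,
                      stringsAsFactors = FALSE)

  mod_of <- stats::setNames(modules$module, modules$gene)[genes_all]
  base_logit <- stats::qlogis(config$p0)
  targets <- matrix(0L, n_g, length(tf_names),
                    dimnames = list(genes_all, tf_names))
  for (tf in tf_names) {
    lp <- rep(base_logit, n_g)
    hit <- config$planted$tf == tf
    for (m in config$planted$module[hit])
      lp[!is.na(mod_of) & mod_of == m] <- base_logit +
        config$planted$log_or[hit & config$planted$module == m][1]
    targets[, tf] <- stats::rbinom(n_g, 1L, stats::plogis(lp))
  }

  w <- config$window_bp; sl <- config$site_len
  rows <- which(targets == 1L, arr.ind = TRUE)
  if (nrow(rows)) {
    off <- sample.int(w + w - sl + 1L, nrow(rows), replace = TRUE) - (w + sl)
    s <- tss_pos[rows[, 1L]] + off
    tfbs <- data.frame(tf_name = tf_names[rows[, 2L]],
                       chrom = rep(config$chrom, nrow(rows)),
                       start = as.integer(s), end = as.integer(s + sl),
                       stringsAsFactors = FALSE)
    tfbs <- tfbs[order(tfbs$tf_name, tfbs$start), , drop = FALSE]
  } else {
    tfbs <- data.frame(tf_name = character(), chrom = character(),
                       start = integer(), end = integer(),
                       stringsAsFactors = FALSE)
  }

  truth <- list(seed = seed, n_tf = length(tf_names), p0 = config$p0,
                window_bp = w,
                planted = config$planted)
  list(genes = genes, tfbs = tfbs, targets = targets, modules = modules,
       truth = truth)
}
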
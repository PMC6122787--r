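# seasonrhythm

Circannual (seasonal) rhythm analysis for cognitive-aging cohort data:
cosinor regression of cognition and CSF biomarkers on calendar date,
seasonal logistic models of MCI/dementia odds, group-modulated rhythm
comparisons, gene co-expression module rhythmicity with permutation-based
family-wise error control, and transcription-factor binding-site proximity
enrichment — plus a fully seeded synthetic-cohort generator so every stage
is testable by parameter recovery without access to restricted cohort data.

## Who it is for

Biostatisticians and neuro-epidemiologists asking whether an outcome
measured once per participant across the calendar year (composite
cognition, a clinical diagnosis, a CSF analyte, a postmortem expression
summary) carries an annual rhythm, how big that rhythm is relative to
overall variability, and when it peaks.

## The model

The core is a free-phase single-component cosinor. A date is mapped to an
angle θ ∈ [0, 2π) over a 365.25-day period (origin Jan 1), and the outcome
is regressed on the quadrature pair plus covariates:

```
y = β₀ + β_c cos θ + β_s sin θ + γᵀz + ε
```

Amplitude and acrophase follow from the coefficients,

```
A = √(β_c² + β_s²),   φ = atan2(β_s, β_c),
```

with the nadir half a period from the acrophase. Rhythmicity is the 2-df
nested F-test against the model without the quadrature pair; amplitudes
are standardized by the outcome SD in a reference sample; confidence
intervals come from a participant-level percentile bootstrap; and the
seasonal swing is optionally re-expressed as the equivalent difference in
years of age, `2A / |β_age|`.

On the diagnosis side, logistic models quantify the winter/spring
(January–June) vs summer/fall (July–December) odds ratio of MCI/dementia
with likelihood-ratio tests. On the molecular side, gene co-expression
modules are summarized as mean member-gene z-scores, scanned for
rhythmicity and for association with cognition proximate to death, with
max-statistic permutation adjustment across modules, and selected when a
module is (1) rhythmic, (2) within two months of the cognition acrophase
or nadir, and (3) cognition-associated — the selected modules are then
tested for enrichment of transcription-factor targets (TSS within
2,000 bp of a binding site; one multivariable logistic model per module;
Bonferroni α = 0.05/161).

## Worked example

```r
library(seasonrhythm)

sim <- generate_cohort(seasonal_preset("combined"), seed = 17)
fit <- fit_cosinor(sim$data, "outcome",
                   c("age_years", "sex", "education_years"),
                   cohort_col = "cohort")
fit <- bootstrap_ci(fit, B = 1000, seed = 17)
print(fit)
#> Cosinor fit: outcome ~ cos + sin + age_years + sex + education_years
#>   n = 2761 (dropped 0 incomplete)
#>   amplitude       0.0514 (0.114 SD)
#>   acrophase       day 260.2   nadir day 77.6
#>   rhythmicity     F(2, 2754) = 10.904, p = 1.92e-05
#>   amplitude 95% CI [0.0318, 0.0722]

age_equivalent(fit)$years
#> 3.9  (bootstrap 95% CI 2.4 to 5.6 years)

season_odds_ratio(sim$data, "mci_dementia",
                  c("age_years", "sex", "education_years"),
                  cohort_col = "cohort")
#> Winter/spring (Jan-Jun) vs summer/fall (Jul-Dec) odds of diagnosis:
#>   OR 1.333 [1.130, 1.573], Wald p = 0.0006626, LRT p = 0.0006486
```

Reading the output: this simulated cohort of 2,761 carries a true
standardized amplitude of 0.14 SD peaking on day 266 (mid-September); the
single-replicate fit estimates 0.114 SD peaking day 260, i.e. the
composite cognition of a person assessed at the September peak is about
0.1 SD (here ≈ 3.9 years of aging) higher than one assessed at the March
trough, and the odds of an MCI/dementia classification are ~33% higher in
January–June (true generating OR 1.31). Averaged over 50 replicates these
estimates recover the generating values — that is what
`scripts/acceptance.R` measures.

The expression pipeline runs the same way end to end:

```r
es  <- generate_expression(seed = 1)
res <- run_module_selection(
  es$mat, es$modules, es$meta,
  covariates = c("age_death", "sex", "education_years", "death_hour",
                 "pmi_hours", "batch", "rin"),
  cognition_col = "cognition", cognition_acrophase_date = 266,
  n_perm = 1000, seed = 11)
subset(res$selection, selected_flag)   # the four planted modules
```

## Command line

A thin CLI wraps the main entry points:

```sh
seasonrhythm simulate --preset combined --seed 1 --out dir/
seasonrhythm cosinor  --input dir/data.tsv --outcome outcome \
    --covariates age_years,sex,education_years --bootstrap 1000 --seed 17
seasonrhythm logistic --input dir/data.tsv --mode categorical \
    --outcome mci_dementia --covariates age_years,sex,education_years
seasonrhythm modules  --expr expr.tsv --modules defs.tsv --meta meta.tsv \
    --nperm 10000 --seed 7
seasonrhythm tfenrich --genes genes.bed --tfbs tfbs.bed --modules defs.tsv
```

See `vignettes/seasonal-rhythms.Rmd` for the statistical details, the
design choices, and what the synthetic generators do and do not emulate.
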
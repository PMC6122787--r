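---
title: "Detecting circannual rhythms in cognition, biomarkers, and brain gene modules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting circannual rhythms in cognition, biomarkers, and brain gene modules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seasonrhythm)
```

## The problem

Cognitive performance in older adults, the odds of being classified as
having mild cognitive impairment or dementia, cerebrospinal-fluid amyloid
levels, and the expression of co-regulated gene sets in prefrontal cortex
all appear to vary with the season in which each person happens to be
measured. Each participant contributes (in the primary design) one
observation per annual cycle, so the rhythm must be estimated
cross-sectionally: the calendar date of assessment, lumbar puncture, or
death becomes an angular covariate, and the question is whether the outcome
follows an annual cosine in that angle, how large the swing is relative to
the outcome's overall variability, and when it peaks.

## The cosinor model

`fit_cosinor()` implements the single-component cosinor: dates map to
angles $\theta = 2\pi\,d/365.25$ (fractional 0-based day of year $d$;
origin January 1, 00:00) and the outcome is fit by ordinary least squares

$$ y = \beta_0 + \beta_c \cos\theta + \beta_s \sin\theta + \gamma^T z
   + \varepsilon . $$

Writing the seasonal part as $A\cos(\theta - \phi)$ gives
$A = \sqrt{\beta_c^2+\beta_s^2}$ and $\phi = \mathrm{atan2}(\beta_s,
\beta_c)$. Fitting the *pair* of quadrature terms rather than a single
fixed-phase cosine is essential: with one term the peak could only sit at
a pre-chosen date, whereas the quadrature pair lets the acrophase land
anywhere (the fitted peaks in this problem domain fall near the fall
equinox, not at a solstice). The price is a 2-df test: rhythmicity is
assessed by the nested F-test of the full model against the model with
both quadrature terms removed. Under the null this p-value is uniform,
which the test suite verifies by simulation (1,000 null fits,
Kolmogorov–Smirnov at $\alpha = 0.01$).

Assumptions worth stating explicitly: one observation per participant
(the caller selects a wave before fitting; repeated waves of the same
person fall at nearly the same calendar date in these cohort designs, so
pooling cycles would add little information while breaking independence);
independent Gaussian residuals; covariate effects linear and additive;
and a purely sinusoidal annual shape — a skewed or double-peaked seasonal
pattern would be absorbed only partially.

### Parameters and conventions

* **Period** — fixed at 365.25 days. Day-of-year comes from the actual
  calendar date, so December 31 of a leap year wraps into (nearly) the
  same angle as in other years; the residual distortion is below 0.3% of
  the circle and no explicit leap correction is attempted.
* **Standardized amplitude** — $A$ divided by the outcome SD over a
  reference sample (`sd_ref`), by default the analysis sample itself.
  When a model is fit on a non-baseline wave but the convention calls for
  standardizing by the baseline SD, the caller passes `sd_ref`.
  Units: SD of the outcome.
* **Age equivalence** — the peak-to-trough difference $2A$ divided by the
  absolute age slope from the *same* model, in years. An age slope below
  $10^{-8}$ in absolute value is treated as degenerate and flagged rather
  than silently returning a huge number.
* **Confidence intervals** — percentile bootstrap, default
  $B = 1000$, resampling participants (rows when no id column is given).
  The interval method in the source literature is unstated; the
  percentile bootstrap was chosen because the amplitude is a nonlinear,
  boundary-constrained ($A \ge 0$) function of the coefficients, for
  which Wald/delta intervals misbehave near zero amplitude — and the
  asymmetric intervals printed in that literature are consistent with a
  resampling method. Rank-deficient resamples are redrawn (capped,
  counted). Degenerate noise-free data collapse the interval to a point,
  which the tests assert.
* **Missing data** — strict complete-case per model, with the dropped-row
  count carried in the fit (`n_dropped`); adjustment sets with different
  availability therefore have different `n_used`, which the confounder
  sweep reports per row.
* **Hour-of-day covariates** (test hour, death hour) enter as categorical
  1-hour bins; cohort and batch as fixed-effect indicators.

### Diagnosis models

`fit_seasonal_logistic()` applies the same quadrature pair on the
log-odds scale with a 2-df likelihood-ratio test. `season_odds_ratio()`
uses the categorical contrast — winter/spring is January–June,
summer/fall July–December — and reports `exp(β)` with a Wald 95% CI plus
a 1-df LRT. With no covariates the estimate equals the 2×2 cross-product
ratio exactly (tested to 1e-8). The Wald form for the CI is a design
choice (the source's interval method is unstated); the LRT carries the
significance claim. Complete separation and non-convergence raise errors
naming the offending column; an events-per-parameter ratio below 5 warns.

### Group-modulated rhythms

`fit_group_modulated()` adds a binary group main effect plus
group × cos and group × sin interactions. "Does the group differ in
rhythmicity?" is operationalized as the joint 2-df F-test on both
interaction terms — amplitude and phase differences are not tested
separately, matching the single reported p-value this analysis style
produces. Per-group amplitudes derived from the interaction
parameterization equal those from fitting each group separately when no
covariates are shared (tested to 1e-8).

## Module rhythmicity

Genes are z-scored per gene across samples (sample SD, $n-1$; zero-variance
genes are dropped with a warning), and a module's score in a sample is the
unweighted mean of its member genes' z-scores. The rhythm scan then runs
the covariate-adjusted cosinor per module on the death date; the cognition
scan regresses cognition proximate to death on each module score.

### Family-wise adjustment by permutation

Both scans are adjusted across the 47-module family by the max-statistic
method: for each of `n_perm` null datasets the family's statistics are
recomputed and each observed statistic is compared against the null
distribution of the family *maximum*, with the add-one correction
$(r+1)/(B+1)$. A per-module own-statistic permutation p is reported
alongside and is never larger than the adjusted p.

The two families use different null schemes, and this is a deliberate
design choice:

* **Cognition association** permutes the gene→module assignment vector,
  preserving module sizes — the scheme this analysis tradition states for
  the cognition adjustment.
* **Rhythmicity** defaults to permuting samples against the date design
  (equivalently, shuffling dates), the scheme of the companion
  seasonal-expression methodology that the rhythmicity adjustment builds
  on.

The reason the distinction matters at desk scale: in the synthetic
universe the four planted modules hold 1,441 of 5,000 genes (29%),
versus ~2.6% of a full transcriptome. Label-permuted pseudo-modules
therefore inherit large, coherent chunks of rhythmic factor content, and
the null maximum F becomes heavy-tailed — heavy enough that genuinely
rhythmic modules of the planted effect size are frequently not
family-wise significant, a pathology that the full-transcriptome analysis
does not exhibit. Date permutation preserves the gene-side correlation
structure, destroys only the date relationship, and yields a calibrated
null whose family-wise error the test suite verifies by simulation. Both
schemes are available for either family through the `permute` argument.
The permutation statistic is the F statistic (rhythm) and |t| (cognition);
the alternative statistics one might permute (amplitude, or the p-value
itself) order the modules identically here because every module shares the
same design and degrees of freedom.

### Selection and phase concordance

A module is a candidate link between season and cognition when
(1) its adjusted rhythmicity p < 0.05, (2) its acrophase lies within two
months — period/6 = 60.875 days, strict ≤, on the circle — of the
cognition acrophase (in phase) or of the cognition nadir (antiphase), and
(3) its adjusted cognition-association p < 0.05. Phase concordance is
evaluated on the unadjusted scan acrophases. The module × phenotype grid
uses Spearman correlations (tested against an explicit rank-then-Pearson
oracle), Bonferroni-corrected over the whole grid, with Fisher-z values
for heatmap display.

## TFBS enrichment

A gene's TSS is its strand-dependent 5′ end on 0-based half-open
intervals (`start` for +, `end − 1` for −). A gene is a target of a
transcription factor when its TSS lies inside a binding-site interval or
within 2,000 bp of one; the distance is the coordinate difference to the
nearer edge base, boundary inclusive. The sorted-scan implementation is
verified against an all-pairs brute-force oracle in the tests. Per
module, membership is modeled by one multivariable logistic regression on
*all* TF indicators simultaneously — reading "independent association"
literally — with a per-TF univariable mode behind a flag for sensitivity
analysis. TFs with fewer than 10 targets among analyzed genes are
excluded before fitting (rare indicators are the dominant source of
separation artifacts); coefficients that diverge anyway are flagged
unestimable and excluded from significance calls. Significance uses
Bonferroni α = 0.05/161 by default; the methods tradition mentions both
Bonferroni and permutation for this analysis, and Bonferroni is the more
conservative, assumption-free default for a 161-test family.

## The synthetic world

The generators in `seasonal_preset()` encode the published cohort
summaries as a fixed "stated world":

* **combined** (n = 2,761; ~81% ROS/MAP-like, ~19% MARS-like): composite
  cognition with total SD 0.45, amplitude 0.063 units (0.14 SD), acrophase
  day 266; age slope −0.02625 per year so that the seasonal swing equals
  4.8 years of aging; MCI/dementia prevalence 813/2,761 with a
  winter/spring log-odds shift of log(1.31). The diagnosis intercept is
  calibrated per dataset so the realized-covariate expected prevalence
  matches the target; the seasonal mechanism is categorical by default so
  the categorical OR is directly recoverable (a cosine mechanism is
  available).
* **sds** (n = 271): DRS-like outcome, mean 115, SD 17, amplitude 0.50 SD,
  acrophase day 320 (mid-November; nadir mid-May). Note the source
  material is internally inconsistent here — a 0.50 SD amplitude on an SD
  of 17 implies a ~17-point peak-to-trough difference, not the 8 points
  its prose mentions; the printed amplitude is what this preset encodes.
* **cnc** (n = 321, 176 AD): four analytes with the published pooled
  means/SDs; Aβ42 rhythmic with *pooled* standardized amplitude 0.30
  peaking day 172 (late June), the AD group's amplitude attenuated by a
  factor of 0.5 ("attenuated" is unquantified in the source; one half is
  a visible-but-preserved rhythm) and the per-group amplitudes solved so
  the size-weighted pooled amplitude hits the target; Aβ40/tau/p-tau
  non-rhythmic; AD offsets lower Aβ42 and raise the others. Negative
  concentrations are truncated at zero and counted in the truth file.
* **expression** (5,000 genes × 507 samples, 47 modules): each module has
  a latent unit-variance factor; genes load on their factor with
  $\sqrt{r}$, $r = 0.3$ pairwise. The four planted modules keep the
  published sizes (328/353/390/370) and standardized amplitudes
  (0.44/0.46/0.43/0.46), two in phase with cognition (day 266) and two
  antiphase (day ~83); cognition is built from the four factors with
  loadings ±0.3 (in-phase positive) plus covariate effects and noise.
  Because 47 modules of the published size range cannot fit in a
  5,000-gene desk-scale universe, the 43 background modules draw sizes
  from [20, 80] and leftover genes stay unassigned (the source itself
  leaves 2% unassigned). Batch adds small gene-level offsets; PMI, RIN,
  death hour, and demographics are generated independently.
* **tfbs** (161 factors, baseline target probability 0.08): the target
  indicator matrix is sampled from a logistic model with log-OR 1.0 for
  the five planted TF–module pairs, and binding-site intervals are then
  *constructed* from the sampled indicators (sites placed within the
  window of targeted TSSs, genes spaced so windows never reach a
  neighbor), so the linking step reproduces the truth matrix exactly by
  construction.

Residual SDs are solved from the realized systematic variance so the
total outcome SD matches its target (an infeasible decomposition is a
config error, not a silent clip). Assessment dates are uniform over the
calendar year — the realized date distribution of the source cohorts is
unpublished — and every generator is a pure function of (config, seed),
emitting its generating parameters as ground truth.

What the generators do *not* emulate: longitudinal trajectories and
within-person date correlation; non-sinusoidal seasonal shapes;
count-scale expression with library-size artifacts; realistic
linkage between neuropathology, demographics, and outcomes beyond the
modeled effects; and any genomic realism beyond the geometry the TFBS
linking step needs. A green recovery test therefore establishes that the
estimators recover the parameters of *this* world at the published sample
sizes — it does not validate the biological claims, and real-data quirks
(batch confounding with season of death, informative missingness) are out
of its reach.

## Numerical choices and degenerate inputs

* Constant outcome: amplitude 0, F set to 0, p to 1 (the 0/0 form is
  resolved explicitly), standardized amplitude NA.
* (0, 0) quadrature coefficients: acrophase defined as 0.
* Collinear designs error with the offending column names; the permuted
  scans refuse rank-deficient designs outright.
* Logistic separation is detected by non-convergence or |coef| > 15 on
  the logit scale.
* Spearman p-values use the large-sample approximation (`exact = FALSE`),
  ties handled by midranks.
* Bootstrap and permutation procedures are deterministic given a seed; in
  `permutation_adjust()` the two statistic families run on independent
  seed-derived streams so that a standalone run of either family
  reproduces the corresponding columns of a `statistic = "both"` run.

## Known limitations

Mixed-effects longitudinal rhythm models, multi-component (harmonic)
cosinor, ordinal diagnosis outcomes, and profile-likelihood intervals for
the odds ratio are out of scope. The age-equivalence CI resamples the
ratio, which can be long-tailed when the age slope is imprecise. The
phase-concordance window is a hard threshold; modules sitting near the
boundary flip classification under resampling. At desk scale the
label-permutation null for the cognition family remains heavy-tailed (the
same gene-fraction effect described above), so module selection
sensitivity is bounded by that family rather than by the rhythm family.
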
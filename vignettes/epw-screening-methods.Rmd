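---
title: "Methods: percentile-weight screening for late-onset SGA across growth standards"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: percentile-weight screening for late-onset SGA across growth standards}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epwscreen)
```

## The problem

A routine third-trimester growth scan (here: 34+0 to 36+6 weeks) yields an
estimated fetal weight (EFW) from biometry. Converted to an *estimated
percentile weight* (EPW) under a growth standard, that single number is the
screening score most units use to decide which pregnancies need closer fetal
growth surveillance. The clinical question this package addresses is
comparative: **how well does the EPW, under different growth standards,
predict small-for-gestational-age (SGA) birth — birthweight below the
population 10th percentile at term delivery — and adverse perinatal outcomes
(APOs), and how does the scan-to-delivery interval change that?**

`epwscreen` provides the full chain as tested, reusable parts:

1. EFW formulas from biometry (`efw()`, three bundled regressions);
2. EPW engines for three standard families (`epw_zscore()`,
   `epw_customized()`, `epw_quantile_grid()`);
3. SGA and APO outcome classification (`classify_sga()`,
   `derive_outcomes()`);
4. the screening statistics battery (`auc_delong()`,
   `delong_paired_test()`, `sensitivity_at_fpr()`,
   `two_proportion_test()`, `logistic_or_per_percent()`,
   `stratify_by_interval()`, `apo_detection_by_epw10()`);
5. a synthetic cohort generator (`generate_cohort()`) so the whole pipeline
   can be exercised and validated without access to hospital records.

## EFW formulas

Each growth standard is evaluated with the EFW regression it was built
with. Three formulas ship as JSON parameter files (coefficients transcribed
from their source publications, never hard-coded):

* `hadlock4` — log10-linear in BPD, HC, AC, FL (centimetres);
* `hadlock3` — the HC/AC/FL variant of the same family;
* `stirnemann` — the log-linear HC/AC model used by the INTERGROWTH-21st
  project.

The API takes millimetres everywhere and converts internally per the
formula's declared unit; a single unit convention at the surface prevents
silent ten-fold errors. Formulas live in a registry (`register_formula()`),
so additional regressions can be added without touching the engines.

## Percentile engines

Three parameterization families cover the six standards compared:

**Z-score curve** (non-customized population standards). A log-quadratic
median weight curve $\log m(t) = \log w_{ref} + b_1 (t - t_{ref}) + b_2 (t -
t_{ref})^2$ with a declared dispersion: either a log-scale SD or a
coefficient of variation on the identity scale. Then $z = (T(w) -
T(m(t)))/s(t)$ and EPW $= 100\,\Phi(z)$.

**Customized** (Gardosi methodology). An individualized *term optimal
weight* — a base weight plus additive gram effects of parity, maternal age,
BMI, maternal and paternal height and fetal sex, zero for the reference
mother by construction — is scaled to the scan age by a proportionality
curve (the same log-quadratic family normalised to 1 at term), and the EPW
follows from the z-score against that individualized expectation with a
coefficient of variation.

**Quantile grid** (the WHO-chart representation). Weights tabulated at the
5th, 10th, 25th, 50th, 75th, 90th and 95th percentile levels on a weekly
gestational-age grid. Level weights are first interpolated linearly in days
(the minimal monotone choice; the source charts do not prescribe one), then
the percentile comes from interpolating the *probit of the level* linearly
in weight between the bracketing levels, extrapolating the outermost
segment beyond P5/P95.

Percentiles are reported on the 0–100 scale and clamped to
[0.01, 99.99] so that probit transforms stay finite. All three engines are
strictly monotone in EFW between the clamping rails, mutually inverse with
`weight_at_percentile()` to 0.1 percentile points, and a quantile grid
tabulated from a z-score standard reproduces that standard's percentiles to
within 0.5 points across the P5–P95 span (the probit-in-weight
interpolation of a lognormal quantile function is nearly linear between
adjacent levels).

## Calibration of the bundled standards

The six bundled parameter files (`bundled_standards()`) represent the
standards compared: non-customized and customized MSUH-type, Figueras-type
(customized; no paternal height in its covariate set), INTERGROWTH-21st-type
(Stirnemann formula), WHO-type (quantile grid) and FMF-type (Hadlock HC/AC/FL
formula). Note that the FMF-type standard is treated as non-customized, the
classification used in the comparison it reproduces.

Their source publications do not all print usable coefficient tables, so
the files are explicitly *calibration fits, not transcriptions*: each
records the structural content of its source (family, EFW formula,
covariate set) while location and dispersion were fitted with
`calibrate_standard()` on a 50 000-pregnancy reference synthetic cohort
(seed 760521) so that the cohort EPW distribution reproduces each
standard's published summary — the median exactly, and the P10–P90 spread
through a fitted dispersion. A two-parameter (location/spread) Gaussian fit
cannot also reproduce skewed summaries exactly (the WHO-type row, median
43.1 with P10–P90 of 7.5–74.9, is the clearest case); the median is
prioritised and the residual error is split between the two tails.
`inst/scripts/rebuild-standards.R` regenerates the files end to end.

Covariate effect sizes for the customized standards (about +8 g/cm maternal
height, +3 g/cm paternal height, +11 g per BMI unit, +105/+140 g for parity
1/2+, +130 g for a male fetus, against the reference mother at the cohort
medians) are representative of published customized-standard magnitudes,
not transcriptions.

## Outcomes

SGA at birth is birthweight **strictly below** the 10th-percentile
reference weight at the delivery gestational age (linearly interpolated;
sex-specific when the reference carries sex columns). The same strict-below
rule is used for screen positivity (EPW < threshold) everywhere — one
strictness convention throughout. The APO composite `any_apo` is the union
of five components (5-min Apgar < 7, instrumental delivery for
non-reassuring fetal status, cesarean delivery for NRFS, cord arterial pH <
7.10, stillbirth); SGA itself is not an APO. Where the composite's
convention is ambiguous — whether SGA deliveries are excluded from the
*event definition* or from the *denominator* — the package computes the
union over all deliveries (event-definition exclusion) and reports
percentages against full-cohort denominators, which is the convention every
recomputable published cell is consistent with.

## Evaluation statistics

* **AUC** is the tie-aware Mann–Whitney statistic, variance by DeLong's
  structural-components estimator, Wald 95% CI clamped to [0, 1]. Scores
  are negated internally so AUC > 0.5 always means low percentiles
  discriminate SGA.
* **Paired AUC comparison** uses the DeLong covariance of the paired
  structural components; a standard compared with itself returns p = 1.
* **Sensitivity at a target FPR** picks the *largest* candidate threshold
  whose strict-below FPR does not exceed the target (candidates are the
  observed scores; a conservative choice — the tie policy of the original
  analyses is not stated — with the achieved FPR always reported).
  Sensitivity CIs are Wilson score intervals by default (the original
  method is unstated; Wald is available for comparison).
* **Two-proportion tests** are pooled-variance z-tests, continuity
  correction off by default, matching the raw pairwise comparisons being
  reproduced; no multiple-testing correction is applied, for the same
  reason.
* **Logistic ORs** per one-point EPW increase come from `glm` maximum
  likelihood (convergence 1e-8, at most 100 iterations) with Wald CIs;
  complete separation is detected and reported as an error rather than
  silently fitted.
* **Interval stratification** buckets the scan-to-delivery interval into
  closed day ranges 8–14, 15–21, 22–28, 29–35, 36–42, 43–49. Intervals of
  1–7 or over 49 days have no bucket and are excluded rather than merged.
  Strata where a standard sees a single outcome class are flagged
  not-evaluable instead of failing the run.

Rendered tables round percentages half-up to one decimal, the convention
of the tables being mirrored.

## The synthetic cohort generator

`generate_cohort()` emulates a term singleton cohort with a universal
35-week scan; `cohort_config()` holds every distributional choice. The
defaults are the study conditions the package validates against:

* **Marginals.** Maternal age, BMI (log-normal), maternal and paternal
  height matched to median/IQR targets (33.3 years, 23.2 kg/m², 163 cm,
  176 cm); parity 53/39/8%; 16% smokers; 51.5% male fetuses. Covariates are
  sampled independently — only marginals are known — so customization
  covariates carry *no true signal* in simulated data.
* **Gestational ages.** Scan: rounded normal, median 246 days (35+1), SD
  1.9 d, clamped to 238–258 (routine scans cluster tightly in the
  scheduled week). Delivery: median 280 days, SD 8.2 d, clamped to
  259–294.
* **Fetal size.** A log-quadratic ground-truth median curve through 3310 g
  at 280 days (2495 g at 246 days), log-scale SD 0.11 at the scan and at
  birth, and a ±2.2% log-scale sex effect. These reproduce the target EFW
  median/IQR (2495, 2314–2697 g by Hadlock-4) and birthweight summary
  (3310, 3030–3590 g).
* **Percentile persistence.** Latent scan and birth percentiles are joined
  by a probit-scale Gaussian copula with correlation $\rho(d) = \rho_0
  e^{-\kappa d / 7}$ in the interval $d$ days; defaults $\rho_0 = 0.97$,
  $\kappa = 0.08$/week — the simplest monotone decay, set so stratum AUCs
  run from the low 0.9s at a 1-week interval to about 0.80 at 6 weeks,
  with an overall AUC in the mid 0.8s.
* **Biometry.** `synth_biometry()` inverts the EFW formula: age-appropriate
  measurement proportions, per-measurement log-normal jitter (SD 0.012),
  then one common rescaling so Hadlock-4 reproduces the latent-percentile
  EFW (plus a 2% log-scale measurement error). The HC/AC level is set so
  the Stirnemann model returns about 97% of the Hadlock-4 weight, matching
  the systematic offset between the two formulas; the jitter is what makes
  Hadlock-3 and Stirnemann EFWs differ stochastically from Hadlock-4 on
  the same scan, as in real biometry.
* **SGA and APOs.** The birthweight reference derived from the generator
  (`reference_from_config()`) places the "P10" cut at the configured
  target rate (default 9.4%). APO components are Bernoulli draws at
  configured base rates (0.16–2.4%), inflated by per-component relative
  risks (2.1–3.9) when the latent birth percentile is below 10. Components
  are drawn independently within a record, so the union rate slightly
  exceeds what overlapping real components would give (about 7.5% vs 6.7%);
  per-component rates are matched, the union is not a calibration target.
  Stillbirths receive a birthweight and gestational age like live births,
  since they are classified for SGA alongside them.

**What passing tests do and do not show.** The generator reproduces
marginal summaries, a tunable persistence structure and rate targets; it
does not model covariate–weight correlations (beyond fetal sex),
pathology-driven growth restriction, Doppler findings, preterm delivery, or
correlated APO components. Results on synthetic cohorts validate the
*pipeline arithmetic* — not the clinical performance of any standard, and
the published cohort-level AUCs and detection rates are not reproducible
without the original hospital data. The package therefore checks
calibration bands (all six standards' AUCs inside [0.78, 0.92] at
n = 9585) and qualitative structure (AUC decaying with interval), not the
published point values. One consequence of covariate-inert simulation is
visible in the defaults: customized standards lose a little discrimination
relative to their non-customized counterparts because customization
injects covariate noise without signal.

## Numerical choices and degenerate inputs

* Gestational age is integer days internally; weeks appear only in I/O.
* Percentile clamping at [0.01, 99.99] creates ties only at the rails;
  monotonicity and inversion contracts are asserted away from them.
* The biometry rescaling is a log-scale Newton iteration on a smooth,
  strictly increasing map (machine-precision convergence, bounds 0.70–1.35
  around the age-median proportions; targets outside the physiologic
  envelope raise an infeasibility error).
* Degenerate evaluation inputs fail loudly: single-class labels (AUC,
  sensitivity), complete separation (logistic), misaligned score vectors
  (paired test). Identical score vectors give a paired p of exactly 1.
* Wilson intervals close exactly at k = 0 and k = n so the point estimate
  cannot escape by a floating-point ulp.
* Runs are reproducible bit-for-bit: the run seed feeds a named substream
  per stage, and the manifest records MD5 sums of every artifact.

## Problem sizes used in validation

The bundled validation suite runs cohorts of 300–9585 pregnancies (five
full-size seeds for the calibration-band check), 500 null replicates of
n = 2000 for the paired-test size check, 200 random instances for the
threshold-scan oracle, and a 20 000-resample bootstrap for the small-sample
paired-test oracle. These sizes keep the full suite under a minute while
holding Monte-Carlo error well inside the asserted bands.

## Known limitations

* Bundled standards are calibration fits; absolute percentiles under the
  *actual* published standards require transcribing their full coefficient
  tables into the same parameter-file schema.
* The two-parameter calibration cannot reproduce skewed percentile
  summaries exactly (see WHO-type above).
* Customized-standard functional form is additive-in-grams; sources that
  customize multiplicatively would need a `log`-transform dispersion and
  multiplicative effects (the schema reserves the transform slot).
* The generator's interval distribution is implied by the scan/delivery
  distributions rather than matched to a published interval table, so
  stratum sizes differ somewhat from any particular cohort.
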
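---
title: "Evaluating meropenem PopPK models for precision dosing under CRRT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating meropenem PopPK models for precision dosing under CRRT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Meropenem is cleared predominantly by the kidneys. In critically ill
patients on continuous renal replacement therapy (CRRT) the native clearance
is largely replaced by the extracorporeal circuit, and exposure becomes hard
to predict from dose alone. Model-informed precision dosing (MIPD) addresses
this by predicting a patient's concentration--time profile from a population
pharmacokinetic (PopPK) model, either *a priori* (covariates only, for the
first dose) or by *Bayesian forecasting* (conditioning the model's random
effects on a measured concentration, for dose adjustment during therapy).

Several PopPK models for meropenem under CRRT have been published, but a
model fitted to one small ICU population need not transfer to another. This
package provides the machinery to evaluate candidate models for MIPD
fitness: a declarative model library, a closed-form prediction engine, MAP
Bayesian forecasting, prediction-error statistics with acceptance criteria,
simulation diagnostics (NPDE, pcVPC), and a synthetic-cohort generator that
emulates the covariate, dosing, and sampling structure of a two-center CRRT
cohort so the full workflow can be exercised without access to patient data.

```{r setup}
library(crrtmipd)
```

## The model library

A candidate model is a `poppk_model`: a 1- or 2-compartment disposition
model in clearance--volume parameterization (CL, V1, and for two
compartments Q, V2), typical values ("thetas"), covariate effects, a
log-normal inter-individual variability (IIV) covariance matrix ("omega"),
and one or more residual-error variants ("sigma"). Eight published
candidates for adult CRRT patients ship as JSON files:

```{r}
builtin_models()
```

Covariate effects are limited to four forms — `linear`
(`p + c*(cov - ref)`), `power` (`p * (cov/ref)^c`), `proportional-shift`
(`p * (1 + c*(cov - ref))`), and `categorical-factor` — applied in
declaration order. Anything else in a source publication is approximated by
one of these and noted in the spec file's `provenance` field. Canonical
units are used throughout: time h, concentration mg/L, amount mg, clearance
L/h, volume L, CRRT flow rate mL/h, residual diuresis mL/24 h.

Each shipped spec anchors the model's typical clearance and covariate
relationship to the values published for it; where a source's full
variance tabulation was not available, omega and sigma are set to
representative magnitudes typical of published meropenem models (30--55 %
CV IIV, 15--35 % proportional residual error) and the provenance field says
so. The covariate structure follows the sources: residual diuresis on
clearance (O'Jeanson, Ulldemolins), total CRRT flow rate (Burger), eGFR
(Niibe by Cockcroft--Gault, Hanberg by CKD-EPI), and no covariate for the
rest. At the reference covariates (no residual diuresis, 2,000 mL/h flow,
eGFR-CG 31, eGFR-CKD-EPI 41) the typical clearances are:

```{r}
ref <- c(residual_diuresis = 0, total_flow_rate = 2000,
         egfr_cg = 31, egfr_ckdepi = 41)
sapply(builtin_models(),
       function(n) typical_parameters(load_builtin_model(n), ref)[["CL"]])
```

The spread is striking: most well-transferring models agree at 4.4--5.8
L/h, while the two outliers (1.9 and 15 L/h) were developed in populations
that differ systematically from a typical CRRT cohort and carry a strong
built-in bias.

## The prediction engine

Concentrations are computed from the exact macro-constant solution of the
disposition model with zero-order (infusion) input, superposed over the
dosing history. Intermittent and continuous infusion share one code path: a
continuous infusion is simply a single long zero-order event (one per bag or
rate change). The solution is linear in dose and approaches `rate / CL` at
steady state; near-degenerate eigenvalues (a two-compartment model collapsing
onto a single exponential) are handled by a tiny documented perturbation of
the peripheral rate constant. The engine is verified in the test suite
against an independent stiff ODE integrator at a relative tolerance of 1e-6
over randomized parameter sets.

```{r}
m <- load_builtin_model("ojeanson_2021")
pars <- typical_parameters(m, c(residual_diuresis = 0))
doses <- dose_events(c(0, 8, 16), amount = 1000, duration = 0.5)
predict_concentration(pars, doses, c(1, 4, 7.75, 23.75))
```

## Forecasting arms

Three evaluation arms mirror how the models would be used clinically:

* `a_priori_all` — every measured concentration predicted from covariates
  alone (random effects at zero). This is the initial-dosing scenario.
* `a_priori_occ2_trough` — the same population prediction, restricted to
  the trough of the second dosing occasion.
* `bayesian_occ2_trough` — the random effects are MAP-conditioned on
  exactly one sample, the last measured concentration of the first
  occasion, and the second-occasion trough is forecast with the resulting
  individual parameters. One conditioning sample mirrors the real-world TDM
  scenario; multi-sample conditioning is available through
  `map_estimate()` but is not the default.

An *occasion* is the interval containing at least one measured
concentration between two dosing events; consecutive doses without an
intervening measurement merge into one occasion. For a continuous infusion
without bag changes the rule has no interior boundaries, so each observation
defines its own occasion with boundaries at the midpoints between
consecutive samples — a deliberate design choice, since the occasion
definition presumes discrete dosing events. A *trough* is operationalized
as the last observation within an occasion.

The MAP estimate minimizes the extended-least-squares objective

$$\sum_j \left[\frac{(y_j - f_j(\eta))^2}{g_j^2} + \ln g_j^2\right]
  + \eta^\top \Omega^{-1} \eta,
  \qquad g_j^2 = \sigma_{add}^2 + \sigma_{prop}^2 f_j^2,$$

by a deterministic multistart (eta = 0 plus four fixed jittered starts;
Brent in one dimension, Nelder--Mead with a BFGS polish otherwise;
convergence tolerance 1e-8 on the objective). Single-observation objectives
can be flat, which is why the multistart is fixed rather than random: the
estimate is reproducible bit-for-bit. Two properties of this objective are
worth knowing. First, as omega shrinks the prior dominates and the estimate
is pulled to zero (shrinkage). Second, with proportional residual error the
$\ln g_j^2$ term penalizes larger predicted concentrations, which induces a
small systematic underprediction (a few percent in the median) in forecasts
conditioned on one noisy sample; this is shared by any extended-least-squares
MAP implementation and is visible in the self-simulation results below.

## Accuracy and precision statistics

The per-sample prediction error is symmetric,

$$PE = \frac{c_{pred} - c_{obs}}{(c_{pred} + c_{obs})/2},$$

bounded in (−200 %, +200 %) and scale-free. Model accuracy is the median PE
(MPE) and precision the median absolute PE (MAPE), both in percent, with R's
standard median convention (mean of the central order statistics for even
counts). The 95 % confidence interval of the MPE is a nonparametric
percentile bootstrap resampling whole subjects (1,000 resamples, fixed
seed), which respects within-subject correlation; the CI method is a
package design choice, as is record-level (rather than subject-median)
pooling in stratified summaries. A model is clinically acceptable for
accuracy when −20 % ≤ MPE ≤ 20 % with the CI spanning zero, and for
precision when MAPE ≤ 30 %.

## Simulation diagnostics

`compute_npde()` simulates replicate observation vectors per subject under
the full model (default 1,000), decorrelates observed and simulated vectors
with the simulated mean and the lower-triangular Cholesky root of the
simulated covariance, and maps each observation's rank among its simulations
through the standard-normal quantile. Prediction discrepancies are clamped
to [1/(2K), 1 − 1/(2K)] so no quantile is infinite. Under a correct model
the NPDE are standard normal; the summary reports a t-test of mean zero, a
two-sided chi-square test of unit variance (the "Fisher variance" check),
and a global Shapiro--Wilk p-value. Simulations for the NPDE are drawn
untruncated so the Gaussian decorrelation theory applies.

`compute_pcvpc()` bins observations on time after the most recent dose
(equivalently time since infusion start for continuous infusion; 8
quantile-spaced bins by default, strata processed independently),
prediction-corrects each observation and simulated replicate by the ratio of
the bin-median population prediction to the record's own population
prediction, and compares observed 5th/50th/95th percentiles with 95 % bands
across simulated replicates (default 500). Bins below a minimum occupancy
(default 3) are dropped with a warning. When all subjects share covariates,
doses, and a single observation time per bin, the correction factor is
exactly 1 and the pcVPC reduces to an ordinary VPC.

## The synthetic cohort

`cohort_recipe()` encodes a two-center virtual population: 60 of 73
subjects in center 1 (56 intermittent / 4 continuous infusion, CVVH-dominant
modality mix, continuous residual-diuresis values, 11 richly sampled
subjects) and 13 in center 2 (all continuous infusion, CVVHD at a fixed
2,000 mL/h, residual diuresis recorded in three categories that map to
1,000/500/0 mL/24 h). Targets: median age 60 y (19--89), weight 77 kg
(48--140), height 170 cm, flow rate 2,000 mL/h (1,500--5,700), residual
diuresis median 0 (0--1,500 mL/24 h), 193 samples in total.

Families are log-normal for weight, creatinine, and flow; truncated normal
for age, height, and albumin; zero-inflated log-normal for residual
diuresis — a median of zero with a range to 1,500 forces a point mass at
zero, whose weight (0.62 in center 1) is set so the cohort median is zero.
Spread parameters are moment-matched so the stated range spans the central
99 % of the untruncated family, then draws are rejected outside the bounds.
Dosing templates default to 1,000 mg q8h over 0.5 h (intermittent) and
125 mg/h (continuous, one long zero-order event); sampling is one trough
per occasion with additional early post-infusion samples for the richly
sampled subjects. Real regimens and sampling times were not published, so
the templates are explicit, configurable assumptions. Every generated
subject satisfies the inclusion filter (≥ 24 h CRRT after the first dose,
≥ 2 samples in ≥ 2 occasions) by construction, and generation is a pure
function of the recipe (byte-identical across runs).

What the generator deliberately does not emulate: time-varying covariates
and CRRT interruptions, below-quantification censoring, assay differences
between centers, and informative sampling (samples triggered by clinical
suspicion). Passing calibration tests on these cohorts therefore
demonstrates the internal consistency of the pipeline, not the clinical
transferability of any model.

## A self-simulation study

```{r, eval = FALSE}
cohort <- generate_cohort(cohort_recipe(n_subjects = 73, seed = 1))
models <- lapply(builtin_models(), load_builtin_model)
run <- run_evaluation(run_config(models, cohort, seed = 1))
run$results
summarize_across_models(run)
```

On cohorts generated from the O'Jeanson model, the generating model
evaluates as accurate (MPE within a few percent, CI spanning zero at
study scale) with MAPE near the total variability floor (≈ 28 %), while
the clearance-outlier models fail accuracy grossly. Conditioning on a
single first-occasion trough roughly halves the median-across-models MAPE
for the second-occasion trough and collapses the median MPE toward zero —
the qualitative signature that one TDM sample repairs most of a mismatched
model's bias.

## Numerical choices and known limitations

* **Problem sizes.** Calibration studies in the test suite use cohorts of
  500 subjects for the bias/precision checks, 100 replicate experiments of
  20 subjects for the NPDE type-I rate, and 300--1,000 simulation
  replicates for diagnostics; these sizes give Monte-Carlo error well below
  the effect sizes being asserted.
* **Median-PE offset.** Because individual exposures under log-normal IIV
  are right-skewed, the typical-value prediction exceeds the *median*
  individual concentration, so on self-simulated cohorts the MPE converges
  to a small positive value (+2 to +4 % under realistic variability) rather
  than exactly zero. At n = 73 the bootstrap CI comfortably spans zero; at
  n = 500 it resolves the offset. Zero-bias null checks on very large
  self-simulated cohorts are therefore only approximate — a property of the
  symmetric median PE itself, not an implementation artifact.
* **Degenerate inputs.** Non-PSD omegas are rejected at load; singular
  simulated covariances in the NPDE are ridge-regularized with a warning;
  quantile clamping keeps all NPDE finite; subjects lacking an
  occasion-2 trough are skipped with a logged reason; undefined PEs
  (non-positive concentration pairs) are excluded and counted.
* **Imputation.** Missing model-relevant covariates are imputed with the
  *model population's* median (declared per spec file), so different
  candidate models impute different values for the same subject —
  intentional, as each model should see the data through its own
  development population.
* **Transfer caveat.** All quantitative results in this vignette and the
  test suite are computed on synthetic cohorts. They validate the
  machinery; conclusions about which published model best fits a given ICU
  population require that population's data.
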
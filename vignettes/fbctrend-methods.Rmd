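---
title: "Methods: joint modelling of FBC trends for two-year colorectal cancer risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: joint modelling of FBC trends for two-year colorectal cancer risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the statistical machinery:
the model and its assumptions, the estimation strategy, what the synthetic
cohort generator does and does not emulate, the numerical choices, and the
known limitations. The README shows the user-facing workflow; here we
explain why the pieces are the way they are.

## 1. The model

The package predicts the absolute risk that a patient is diagnosed with
colorectal cancer within two years of their most recent full blood count
(FBC), from the *trends* in their haemoglobin (HB, g/dL), mean corpuscular
volume (MCV, fL) and platelet count (PLT, ×10⁹/L) over the five years up to
that test. Models are fitted to males and females separately throughout.

**Time scale.** Each patient's newest retained FBC (the *baseline*) sits at
time 5 on a five-year longitudinal clock; a measurement taken `d` days
earlier sits at `5 − d/365.25`. Measurements older than the window are
discarded. Risk is then projected two years *forward* from baseline.

**Longitudinal sub-models.** One linear mixed model per analyte:

`y = x(age, t)'β + b₀ + b₁ t + ε`,  `(b₀, b₁) ~ N(0, G)`, `ε ~ N(0, σ²)`.

The fixed design `x` uses linear splines: age at baseline with knots at
60/70/80 years (HB), 55 (MCV) and 60 (PLT); time with a knot at year 3 for
every analyte; and an untransformed age × time interaction for HB only. Age
is constant within a patient (age at baseline), so between-patient age
differences identify the age terms, while the random slope `b₁` carries
each patient's own time trend. `G` is unstructured (2×2), estimated by
REML.

**Trend deviations.** The quantity the survival model acts on is each
patient's model-implied departure from the average population trajectory
*at the baseline time*: `d = b̂₀ + 5 b̂₁`, where `(b̂₀, b̂₁)` is the BLUP
(conditional mean given the patient's residuals),
`b̂ = G Z'(Z G Z' + σ² I)⁻¹ r`. The value-scale deviation (not the slope
alone) was chosen because the published hazard ratios are per analyte
*unit* (per g/dL, per fL), which is the natural unit of a value-scale
departure; a slope-only deviation would be per unit-per-year. Patients with
a single measurement still contribute: their BLUP is simply shrunk heavily
toward zero. Patients with no measurements of one analyte fall back to the
population mean (zero deviation) with a warning, honouring the design's
no-imputation policy.

**Survival sub-model.** A Cox proportional-hazards model with Breslow tie
handling on five covariates: the repeated-power-2 fractional-polynomial age
pair `(a², a² log a)` with `a = age/age_scale`, plus the three trend
deviations in analyte units. Absolute risk uses the Breslow baseline
survival at two years with mean-centred predictors:
`risk = 1 − S₀(2)^exp(lp − l̄p)`.

**Cohort construction.** Eligibility: age ≥ 40 at baseline, ≥ 1 retained
measurement of each analyte, ≥ 1 year registered with the practice.
Measurements outside configurable plausible ranges (defaults HB 3–25 g/dL,
MCV 50–150 fL, PLT 10–1500 ×10⁹/L) are dropped first. All FBCs within the
*exclusion window* before the diagnosis/censor date are then removed, and
the newest survivor becomes baseline. Outcome: diagnosis within the
*outcome window* after baseline is an event; otherwise follow-up is
censored at the earliest exit date, capped at two years.

The "two years ± three months" tolerance creates an asymmetry the package
resolves as: exclusion window = 24 − 3 = **21 months**, outcome window =
24 + 3 = **27 months**. This is the only pairing under which a case can be
diagnosed about two years after their baseline FBC while every more recent
FBC was excluded. Diagnoses later than 27 months are treated as non-cases
censored at 24 months. One rule is applied to cases and non-cases alike.

## 2. Two-stage estimation

The package estimates the joint model in two stages: (1) fit the three
mixed models and extract BLUP deviations; (2) fit the Cox model on those
deviations. A simultaneous maximisation over all six correlated random
effects would require high-dimensional quadrature at every Newton step and
is far beyond desk scale; the two-stage estimator targets the same
estimands and is the package's headline methodological approximation.

Why it is a good approximation here: the BLUP is a conditional expectation,
so the true deviation decomposes as `d = d̂ + e` with `e` independent of
`d̂` under joint normality — Berkson-type error, not classical error. For a
rare outcome the marginal hazard given `d̂` is `h₀ exp(α d̂) E[exp(α e)]`,
and the second factor is absorbed into the baseline hazard whenever
`var(e)` is roughly constant across patients, leaving the log hazard ratio
`α` essentially unattenuated. Heterogeneity in `var(e)` (patients with 1
vs 10 FBCs shrink differently) introduces only a second-order bias. The
acceptance suite measures this directly: across 20 seeded replicates per
sex, the fit's 95% CI covers the generating log hazard ratio in ≥ 90% of
replicates, and at n = 50,000 the recovered HB hazard ratio lands within a
fraction of a percent of the generating value. The three analytes are
fitted as three independent mixed models (block-diagonal across analytes)
rather than one six-random-effect fit; the analytes' random effects are
generated independently and, in the data the design targets, carry little
cross-correlation.

## 3. The synthetic cohort generator

The generator exists so that every downstream stage is testable without
the access-restricted source data. Its central design decision is that
**the joint model itself is the generative mechanism**: random effects are
drawn from the configured `G` matrices, measurements from the mixed-model
mean plus noise, and the event time by inverse-transform sampling from the
Cox hazard whose covariates are the *true* deviations at baseline. This
makes parameter recovery well-posed — the generating coefficients are
exactly the estimand of the pipeline.

Defaults, with provenance:

* **Age**: truncated normal, mean 60.7 / SD 13.0 (males) and 61.9 / 14.6
  (females) on [40, 104/108], rounded to whole years — the published
  cohort's age moments. Whole years keep the generator's `birth_year`
  arithmetic exact through cohort preparation.
* **Visit process**: `1 + Poisson(2.2)` FBC panels per patient (mean 3.2),
  the published measurement-to-patient ratio (~800k haemoglobin results
  over ~251k males); one panel = all three analytes. The guaranteed first
  panel is the baseline FBC at time 5; the rest are uniform on the window.
* **Cox truth**: the published sex-specific hazard ratios, as log-HRs, with
  `age_scale = 1` (see §5). Longitudinal truth (population curves, G
  matrices, residual SDs) is realistic adult haematology chosen once and
  documented in `default_longitudinal_truth()`; it is configuration, not a
  published estimate.
* **Baseline hazard**: constant (exponential), because no baseline form is
  published and the exponential admits closed-form checks (the null-HR
  event rate equals `1 − exp(−2 rate)` exactly). The per-sex rates
  (1.07×10⁻³ and 1.33×10⁻³ per year at the centred linear predictor) were
  calibrated once so a multiplier-1 cohort shows the target ~0.4% (male)
  and ~0.3% (female) marginal two-year event rates, and then frozen.
* **Event-rate multiplier**: 1 by default; recovery experiments use 10,
  because at a 0.35% event rate desk-scale cohorts yield too few events for
  a stable five-covariate Cox fit, and covariate hazard ratios are
  invariant to baseline-rate scaling.
* **Event-time placement**: event times are drawn over the two-year
  horizon, then realised diagnosis dates are mapped monotonically into the
  21–24-month window after baseline. Two facts force this. First, the
  design guarantees no patient is diagnosed or censored within 21 months of
  baseline — otherwise the exclusion window would re-anchor their baseline
  and the generative truth would no longer be the estimand. Second, the
  mapped window must not extend past the 24-month administrative censoring
  time: events later than every censoring time would face case-only risk
  sets, a right-truncation that we measured attenuating all log hazard
  ratios severely before adopting this mapping. A monotone time transform
  preserves the proportional-hazards structure, so the log hazard ratios
  are untouched. Non-cases exit at the earliest of a random practice-exit
  time (rate 0.4/year beyond 21 months, so ~10% leave before the horizon
  and the IPCW Brier correction has real work to do) and an administrative
  end of records.
* **Decoys**: a fraction of patients receive an extra FBC panel *inside*
  the exclusion window (25%), a panel older than the five-year window
  (15%), and ~0.2% of rows are duplicated with impossible values — so the
  preparation stage's filters all operate non-trivially on generator
  output, and the intended baseline is recovered exactly after they run.

With the published age coefficients as truth, simulated cases come out
about ten years older than non-cases, matching the published cohort
pattern without any dedicated tuning — the age-risk gradient implied by the
fractional-polynomial terms produces it.

What the generator does **not** emulate: comorbidity-driven confounding
(e.g. other diseases that depress haemoglobin), practice-level clustering,
informative visit schedules (in reality cases are tested more often close
to diagnosis; the exclusion window exists partly to blunt exactly that),
non-normal laboratory error, and pre-diagnosis trend *ramps* beyond what
the linear random-slope model expresses. Passing recovery tests therefore
demonstrates internal statistical correctness of the machinery, not
real-data performance; the published real-data statistics (c ≈ 0.75,
Brier ≈ 0.003) are not reproducible from synthetic data and are not claimed.

## 4. Numerical choices

* **REML vs ML**: REML, the standard for variance components.
  `lme4::lmer` performs the optimisation; convergence diagnostics are
  surfaced as warnings with the optimiser's messages.
* **Noise-free degeneracy**: if the fixed design interpolates the data
  exactly (residual mean square below 10⁻¹⁰ × the response variance, as in
  zero-noise simulations), variance components are not estimable and the
  fit falls back to ordinary least squares with `G = 0`, returning exact
  fixed effects deterministically.
* **Singular designs** are rejected before fitting, naming the collinear
  columns (QR with pivoting).
* **BLUPs** are computed from the 2×2 system `b̂ = G(σ²I + Z'Z G)⁻¹ Z'r`,
  valid for singular `G` (full-shrinkage limit returns zero), and
  vectorised across patients via per-patient sufficient statistics; the
  vectorised and scalar paths are cross-checked in tests, as is the exact
  2×2 closed form.
* **Breslow baseline**: implemented directly
  (`H₀(t) = Σ d_j / Σ_{risk set} exp(lp)`), cross-checked against
  `survival::basehaz(centered = TRUE)` and, under null covariates, against
  the Nelson–Aalen estimator. A horizon beyond the last follow-up returns
  the last-event estimate with a warning.
* **Ties**: Breslow tie handling in every Cox fit; Harrell's convention for
  concordance (0.5 for tied predictions, tied event times unusable);
  same-day duplicate measurements of one analyte are averaged; "positive"
  at a risk threshold means *strictly above* the cut-off, and percentile
  cut-offs use the inverse-ECDF (type-1) quantile, so under distinct risks
  the flagged fraction is exactly (100 − p)%.
* **D-statistic**: Blom approximation `qnorm((r − 3/8)/(n + 1/4))` for
  expected normal order statistics (the recommended form; error negligible
  for n ≥ 20), scaled by κ = √(8/π); CI from the Cox SE. The pseudo-R²
  uses `R²_D = (D²/κ²)/(π²/6 + D²/κ²)`.
* **Brier score**: IPCW with the Kaplan–Meier estimate of the censoring
  distribution (the named score does not itself specify a censoring
  correction); events weight `1/G(T−)`, horizon survivors `1/G(2)`,
  pre-horizon censorings zero.
* **Rounding**: printed accuracy percentages round half-up to 2 dp (not
  banker's rounding), matching how published tables are typeset.
* **Serialisation**: model bundles are JSON with doubles written at 17
  significant digits, so a re-read bundle reproduces predictions bit for
  bit (verified in tests).
* **Determinism**: all generator randomness flows from the config seed;
  mixed-model and Cox fits have no stochastic initialisation, so repeated
  fits agree bitwise.

## 5. Open design points and how they were resolved

* **FP age scaling**: the exact scaling convention behind the published age
  hazard ratios (1.015, 0.997 per unit of the FP terms) is not recoverable
  from the text. The package defaults to `age_scale = 1` (terms `age²`,
  `age² log age` in years), under which those coefficients imply a log
  hazard rising steeply from age 40 to a plateau around 85 — a clinically
  sensible gradient that also reproduces the ~10-year case/non-case age
  gap. `age_scale` stays configurable so published coefficients under any
  convention can be slotted in; exact reproduction of the published age HRs
  is not claimed.
* **Value vs slope deviation**: value-scale (`b₀ + 5b₁`), for the
  unit-compatibility reason in §1; only this variant is implemented.
* **Platelet units**: printed sources are inconsistent between 10⁹/L and
  10¹²/L; the package labels platelets 10⁹/L (the conventional unit) and
  treats the label as cosmetic — coefficients are per platelet unit either
  way.
* **c-statistic variant**: Harrell's c on the censored survival outcome is
  the default; a binary two-year AUC is available through `roc_curve()` on
  the event indicator, and the two provably coincide when no censoring
  occurs before the horizon.
* **Thresholds**: percentile cut-offs are computed on the cohort being
  evaluated (the natural reading when development and evaluation cohorts
  differ).
* **Censored non-events in confusion tables** count as negatives: published
  threshold rows sum to the full cohort size, which forces that coding.

## 6. Problem sizes

The test suite runs recovery at 20 replicates × 5,000 patients per sex
(coverage of a nominal-95% CI is sample-size independent for an unbiased
estimator, so desk-scale replicates check the same property as larger
ones), the calibration-slope identity at 20,000 patients, and vigintile
calibration at 10,000. The acceptance script runs the single-seed recovery
targets at the full 50,000 patients per sex with the 10× inflated baseline
hazard (~1,600–2,000 events each) and the slope target at 20,000. A full
pipeline fit at 50,000 patients (three REML fits on ~160,000 rows plus the
Cox stage) takes on the order of half a minute on one CPU.

## 7. Known limitations

* Two-stage estimation is an approximation to full joint maximisation; its
  bias is negligible for rare events (§2) but would grow for common
  outcomes or strongly heterogeneous measurement counts.
* The generator's realism limits (§3) mean external validity claims cannot
  be made from this package alone; the pipeline is designed so that the
  restricted real data could be substituted for the generator without
  touching any downstream stage.
* Standard errors of the longitudinal fixed effects are not propagated into
  the Cox stage; with ~10⁵–10⁶ measurements the first-stage uncertainty is
  dominated by the second-stage partial-likelihood SE.
* Competing risks (death before diagnosis) are treated as censoring, as in
  the underlying design; a Fine–Gray variant is out of scope.
* The hazard model is proportional by construction and is only evaluated
  at the two-year horizon; time-varying effects beyond two years are out of
  scope.
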
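---
title: "Methods: temporal validation of lipid screening models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: temporal validation of lipid screening models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidval)
```

`lipidval` implements the external-validation workflow for two
diagnostic logistic models that screen young adults (20–40 years) for
elevated LDL-C and elevated non-HDL-C, both defined at ≥ 160 mg/dL.
This vignette is the package's account of the statistical methods, the
choices that were genuinely open, and what the shipped simulations do
and do not demonstrate.

## The models and their validation metrics

Each screening model is a logistic equation over at most three
predictors — gender (male = 1), metabolic age (years, a BIA-derived
body-composition summary), and diastolic blood pressure (mmHg):

```{r}
ldl_model()
nonhdl_model()
```

Validation of such a model on a labeled cohort rests on four
quantities, all computed by `validate_model()`:

* **AuROC** — the Mann–Whitney concordance probability, with ties
  counting one half. The variance is DeLong's; published external
  validations rarely state their CI estimator, so DeLong is the
  package default and the test suite cross-checks it against an
  independent implementation (pROC) and against brute-force pairwise
  concordance. Discrimination wording follows the usual logistic
  textbook bands (≤ 0.7 poor, ≤ 0.8 acceptable, ≤ 0.9 excellent).
* **Calibration-in-the-large (CITL)** — the ML intercept of
  `logit P(y=1) = a + LP` with the linear predictor as a fixed offset.
  Zero means overall observed risk matches overall predicted risk.
* **Calibration slope** — `b` in `logit P(y=1) = a + b·LP` with the
  intercept re-estimated jointly. Slopes below 1 mean predictions are
  too extreme. Both calibration models are fitted with `stats::glm`;
  Wald CIs are reported on the estimation scale.
* **E:O ratio** — mean predicted risk over observed event rate, with
  `SE(ln E:O) = sqrt((1−φ)/(nφ))` and a log-normal CI.

`calibration_curve()` renders either equal-count quantile bins with
exact binomial CIs (default 10 bins, requiring n ≥ 10 per-bin-count)
or a local-linear loess smoother (span 0.75 by default; the source
material does not state its span, so it is a documented assumption).

## Recalibration and refitting

`recalibrate()` performs standard logistic recalibration: estimate
`(α, β)` in `logit P = α + β·LP`, then fold them back
(`coefficients ← β·coefficients`, `intercept ← α + β·intercept`). Two
procedures are implemented because the description "recalibration
according to the C-slope and CITL" is ambiguous:

* **joint** (default): `(α, β)` by joint maximum likelihood. On the
  recalibration data themselves this forces slope = 1 and CITL = 0
  exactly (first-order conditions), which the tests verify to 1e-6.
* **sequential** (`method = "sequential"`): slope first, then the
  intercept with the rescaled LP as offset. This zeroes the same-data
  CITL but leaves the same-data slope slightly off 1 — the pattern a
  validation report shows when its post-update slope is near, but not
  exactly, 1. It is exposed for sensitivity analysis rather than
  default use.

Coefficients are never rounded internally; `emit_equation()` rounds to
four decimals at rendering time only. `refit()` re-estimates all
coefficients from the validation data (no variable selection, no
shrinkage — deliberately, since the strategy's purpose is plain
coefficient re-estimation); nesting of the three log-likelihoods
(refit ≥ recalibrated ≥ original) is enforced by construction and
checked in the tests.

## Decision-curve analysis

`net_benefit(y, p, t) = (TP − FP·t/(1−t))/n` with positivity defined
as `p ≥ t`; ties count as positive (the convention is fixed and
documented because source figures do not resolve it). The comparators
are screen-all (`φ − (1−φ)·t/(1−t)`) and screen-none (0), and the net
reduction in investigations is reported **per 100 participants**:
`(NB_model − NB_all)/(t/(1−t)) × 100` — the per-100 scale matching the
figure axes this mirrors, not a percentage of tests. The default
threshold grid is 0.01–0.60 in steps of 0.01, covering the clinically
discussed 10–50% range with margin, and curves are not smoothed.

## Minimum sample size for external validation

`validation_sample_size()` assembles three precision criteria, each
returning the smallest n whose anticipated 95% CI width meets its
target, with tightness verified (n passes, n − 1 fails):

* **C-statistic**: Newcombe-type variance of the concordance
  statistic, at the anticipated AuROC and prevalence; solved by binary
  search.
* **Calibration slope**: the Fisher information of the (intercept,
  slope) logistic recalibration model, integrated over an assumed
  `LP ~ Normal(μ, σ²)` with 200-node Gauss–Hermite quadrature
  (Golub–Welsch nodes; the integrands are smooth and the quadrature is
  accurate far below 1e-12, verified against dense trapezoidal
  integration in the tests). Reference implementations of this
  criterion typically integrate by Monte-Carlo simulation of a 10⁶
  pseudo-cohort; the deterministic quadrature used here agrees with
  such simulation-derived values to a few parts per thousand, which is
  exactly the scale of their simulation error.
* **O/E ratio**: `SE(ln O/E) = sqrt((1−φ)/(nφ))`. The default targets
  a symmetric interval **on the O/E scale**, solving
  `2·OE·sinh(z·SE) = width`; the simpler delta-method convention
  (`2·z·OE·SE = width`) is available via `oe_width_scale = "log"`. The
  two differ by a handful of participants at typical widths, and
  published minima can fall between them.

Prevalence can be given as a rounded proportion or an exact
`c(events, n)` fraction; the returned integers are sensitive to this
at the ±5 level. The shipped configurations
(`samplesize_spec_ldl()`, `samplesize_spec_nonhdl()`) use the rounded
pre-specified inputs (13.6% / 19.7%) by default, with
`exact_prevalence = TRUE` switching to the development-cohort
fractions (303/2222, 1013/5149):

```{r}
validation_sample_size(samplesize_spec_ldl())
```

## Case-mix benchmarking and the strategy matrix

`casemix_reference()` answers "what performance could this model at
best achieve in this population if its coefficients transferred
perfectly?": resample participants with replacement, simulate outcomes
from the model's own predicted risks, recompute AuROC/C-slope/CITL,
repeat B times (default 1000), and report means with 2.5/97.5
percentile CIs. Because outcomes are generated from the model, the
slope centers on 1 and CITL on 0 by construction; the AuROC reflects
the case-mix (spread of predicted risk) alone and is provably
unaffected by the cohort's observed outcomes — the tests verify
invariance under outcome permutation. Replications where the simulated
outcome is single-class or the fit fails are skipped and counted; more
than 10% skips aborts with an error (small-cohort, low-prevalence
settings make the benchmark unreliable before they make it wrong).
Which equation seeds the simulation is genuinely ambiguous in
before/after-update comparisons, so it is exposed (`seed_model`);
`strategy_matrix()` seeds each column with the model being scored in
it, which reproduces the characteristic drop of the reference AuROC
after an update.

`strategy_matrix()` lays out temporal validation (before/after
recalibration), the case-mix reference, same-data refitting (after
stage only), and validation with metabolic age replaced by its linear
proxy. `evaluate_imputation()` summarizes measured-vs-estimated
metabolic age agreement as R², mean residual (linear CITL) and the
observed-on-estimated slope.

## Fairness assessment

`fairness_report()` examines heterogeneity of AuROC, C-slope and CITL
across subgroups: gender, tertiles of age, BMI, metabolic age and DBP,
the ten ISCO-08 occupation major groups, and (when the columns exist)
fat/muscle percentage and waist-to-height ratio. Subgroup AuROC
conditions on the covariate (computed within each subgroup); subgroup
calibration uses the saturated-interaction binomial model
`logit P = Σ_g 1[g](a_g + b_g·LP)`, whose estimates coincide with
independent per-group fits (verified to 1e-6). Exact cut points for
the continuous covariates are not published, so tertiles are the
documented default and the cuts travel with the output. Subgroups with
fewer than 20 participants or fewer than 5 events are flagged rather
than suppressed — Wald CIs are unstable there — and single-class
subgroups are flagged, never dropped silently.

## The synthetic cohort generator

No participant-level data are deposited for this population, so the
generator is the package's test bed. It emulates:

* the validation-wave marginals (22.7% male; age 30.4 (4.7) y; BMI
  22.9 (4.5) kg/m²; metabolic age 31.0 (12.6) y; DBP 70.4 (10.1) mmHg;
  SBP 115.5 (13.2) mmHg), drawn as independent truncated normals —
  truncation by rejection resampling (hard clipping would create
  probability atoms) at plausibility bounds: age in the 20–40
  eligibility window, BMI > 12, DBP > 35, SBP > 60, metabolic age > 0;
* the eligibility flow: ICD-10 prefix exclusions (E78, E03, F50, N04,
  Z34), lipid-affecting medications (statins, ezetimibe, PCSK9
  inhibitors, fibrates, thiazides, glucocorticoids, amiodarone,
  cyclosporin), age window — with one primary reason logged per
  exclusion, priority icd10 → medication → age;
* outcomes `y ~ Bernoulli(expit(a + b·LP))` under a configurable
  true drift `(a, b)`, so miscalibration recovery is testable with
  known truth. Binary endpoints always come from this logistic
  mechanism, never from thresholding a continuous lipid draw (the
  optional `include_lipids` columns are descriptive cosmetics only).

What it does **not** emulate, hence what passing tests cannot show
about real data: joint correlation among predictors (only marginals
are published; an independence copula is the honest default, and
metabolic age can alternatively be generated from its age/BMI/gender
proxy plus noise via `metage_mode = "eq3_plus_noise"`), measurement
error in BIA and blood-pressure readings, within-worksite clustering,
and any real biological link between the predictors and lipid levels
beyond the assumed logistic form. The ISCO occupation mix (default
weighted toward professionals, technicians and service workers, the
composition of a hospital workforce) is a modelling choice, not a
published table.

Two generator conventions deserve note. The default
`metage_noise_sd = 4.5` years in eq3 mode puts the measured-vs-proxy
R² near 0.87, the agreement regime reported for this proxy — the
tests verify the generator lands there. And in eq3 mode metabolic age
inherits the proxy's unclamped range: the linear proxy is negative
for extreme young/lean/male inputs by design (documented, not
clamped), so the positivity truncation applies only to the
direct-normal mode.

## Numerical choices

* Inverse logit branches on the sign of LP, so |LP| > 700 cannot
  overflow; probabilities are clipped to [1e-12, 1 − 1e-12] before any
  logit. Round-tripping `logit(expit(LP))` is exact to 1e-9 only for
  |LP| ≲ 12 — beyond that a double storing p has discarded the
  information — and the tests respect that domain.
* Separation: a `glm` fit is reported as an estimation error (never a
  silent huge slope) when the fitted probabilities perfectly separate
  the classes or any coefficient exceeds 30 in absolute value. Note
  that quasi-separated configurations (classes overlapping at a single
  LP value) have no finite MLE either; the likelihood's supremum is at
  infinite slope, and the divergence check is what catches them.
* Tie-break in decision curves: `p ≥ t` counts as test-positive.
* Seeds: one root seed per run; each stochastic stage (cohort draws,
  outcome simulation, bootstrap) uses a child seed derived by a fixed
  multiplicative-hash scheme (`lipidval:::derive_seed`), so inserting
  a stage never perturbs another stage's draws, and equal configs give
  byte-identical outputs.

## Problem sizes used by the test suite

Moment-recovery and drift-recovery properties run at n = 20,000
(sampling SE well below the asserted tolerances); coefficient-recovery
refits at n = 50,000 (±10% bands); MLE identities at n = 4,000–8,000
(they are exact identities, size only affects conditioning); the
case-mix benchmark property at the reported replication setup
B = 1000, n = 1099. Replicate-averaged checks (5–10 replicates) are
used where a single draw would make the test itself a ~95%-probability
event. These sizes are the package's own choices, balancing
Monte-Carlo error of the checks against brute speed.

## Known limitations

* The shipped equations are the *updated* models; the pre-update
  development coefficients are not published alongside them and are
  treated as user input (`read_model()`), never back-derived.
* Calibration CIs are Wald-type; profile likelihood is not
  implemented.
* No Hosmer–Lemeshow test, Brier score, bootstrap CIs on net benefit,
  or cost-effectiveness layer; no penalized refitting; no geographic
  (multi-site) validation design.
* The fairness module reports heterogeneity; it deliberately does not
  correct for it (per-subgroup recalibration is a modelling decision
  the user must own).
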
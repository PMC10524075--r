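---
title: "Evaluating triage screening tests: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating triage screening tests: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fitriage)
```

`fitriage` evaluates two-stage cancer-screening designs in which a
questionnaire-based risk assessment (RA) and a fecal immunochemical test
(FIT) act as the initial filter before colonoscopy, and pools
diagnostic-accuracy evidence across studies with a bivariate
random-effects model. This vignette is the package's own account of the
methods: the models and their assumptions, the parameters that matter,
the numerical decisions, and what the test suite does and does not
establish.

## From a screening cohort to 2×2 tables

### The decision rule and the strategies

A participant is high risk when **any** of three major questionnaire
items is positive (history of any cancer, history of colorectal polyps,
colorectal cancer in a first-degree relative) **or at least two** of six
minor items are (chronic constipation, chronic diarrhea, mucus/bloody
stool, serious adverse life event, chronic appendicitis/appendectomy,
chronic cholecystitis/cholecystectomy). `assess_risk()` implements
exactly this rule and nothing else; the test suite checks it against a
brute-force re-evaluation on all `2^9 = 512` response profiles.

Seven initial-test strategies are formed from the RA result and the two
FIT specimens (`strategies()`). *Parallel* means positive if any
component is positive; *serial* means positive only if all components
are. The 2-specimen FIT is itself a parallel composite: positive when
either specimen is. Two readings of "serial RA + 2-specimen FIT" are
defensible — RA positive **and** any specimen positive, or RA positive
**and both** specimens positive. The published positive counts equal the
RA-and-any-specimen reading, so that is the default;
`combine_tests(..., serial_both_specimens = TRUE)` gives the stricter
one. We deliberately do not guess beyond the count match.

### Outcome classification

Case ascertainment in such programmes comes from registry linkage, so a
"case" is defined by the diagnosis lag, not by colonoscopy at screening:

* positive screen, diagnosis within `screen_detected_days` (default 90) —
  **screen-detected**;
* positive screen, diagnosis after that but within `case_horizon_days`
  (default 365) — **missed** (in practice: non-adherence to colonoscopy);
* negative screen, diagnosis within the horizon — **interval**;
* otherwise a **non-case**.

Two deliberate choices. First, the interval definition has *no lower
bound*: a screen-negative subject diagnosed at day 10 is an interval
case. Second, the default horizon is 365 days; a 2-year horizon is
sometimes used for supplemented cases, and `outcome_windows()` makes the
horizon configurable, but the published accuracy tables we reconstruct
are defined on the 1-year interval. Episodes, not subjects, are the unit
of analysis: a participant screened in several waves contributes one row
per episode, matching denominators counted in tests. A strategy that
needs a missing FIT specimen is an error, not an imputation — the
programme mandated two specimens, so absence is a data defect.

`tabulate_strategies()` then counts: true positives are positive cases
(screen-detected or missed), false negatives are interval cases, and
non-cases split by test result. The total is invariant across
strategies, and the parallel RA + 2-specimen FIT positives are a
superset of every other strategy's positives — both are property-tested.

### Accuracy indices

`accuracy_summary()` reports sensitivity, specificity, PPV, detection
rate per 1000 tests, LR⁺, LR⁻ and AUC. Conventions:

* **Proportion CIs**: the source tables do not name a method; the
  default is the Wilson score interval (`stats::prop.test` without
  continuity correction), with exact Clopper–Pearson as an option. Point
  estimates reproduce the published tables exactly; CI bounds agree to
  about ±0.01 but are not treated as ground truth.
* **LR CIs**: Simel's log method,
  `se(ln LR+) = sqrt((1−sens)/tp + spec/fp)`; a zero cell triggers a 0.5
  correction of all four cells, flagged in the output. A
  false-positive rate of exactly zero reports `LR+ = Inf` with
  `lr_infinite = TRUE` rather than failing.
* **AUC of a single binary test**: the trapezoidal area through (0,0),
  (1−spec, sens), (1,1), i.e. `(sens+spec)/2`. A binary test has no ROC
  curve proper, and the source never defines its single-test AUC; this
  is documented as a convention, not an estimate of anything else.
* **Rounding** happens only at serialisation (`format_accuracy()`,
  `write_report()`), half-up at the printed precision, because base
  `round()` is half-to-even and disagrees with printed tables at .005
  boundaries. Internal values stay at full precision.

## The bivariate meta-analysis stack

### The model

Study *i* contributes `y_i = (logit sens_i, logit spec_i)`. The model is
the standard bivariate normal–normal hierarchy:

```
y_i | θ_i ~ N(θ_i, S_i),   θ_i ~ N(μ, Σ)
```

with `S_i = diag(1/tp + 1/fn, 1/tn + 1/fp)` and
`Σ = [[τ²_s, ρτ_sτ_e], [ρτ_sτ_e, τ²_e]]`. The default fit is REML with
the fixed effects profiled out by GLS, so optimisation runs over
`(τ_s, τ_e, atanh ρ)` only. The literature's software for this model is
not re-derivable from its description, so the package fits the standard
model and rests its validity on parameter recovery from its own
generator and on agreement with an independent multivariate REML
implementation (`metafor::rma.mv`, used in the tests as a cross-check,
never as the implementation).

Numerical choices:

* **Continuity correction**: 0.5 added to all four cells of any study
  containing a zero cell — per-study, not global; configurable via
  `correction`.
* **Optimiser**: bounded L-BFGS-B from six deterministic starts (one
  moment-based, five fixed grid points), `pgtol = 1e-8`, `τ ∈ [0, 5]`,
  `|ρ| ≤ 0.999` via the `atanh` transform. The best finite optimum
  wins; if every start fails the fit errors rather than returning
  garbage.
* **`τ` at the boundary**: variances are floored at 0 by the box
  constraint; a fit with both variances (near) zero degenerates the
  sROC to its summary point, with a warning.
* **Exact-binomial option** (`method = "ml_binomial"`): keeps
  `tp ~ Bin(tp+fn, sens_i)`, `tn ~ Bin(tn+fp, spec_i)` and integrates
  the bivariate random effect by Gauss–Hermite quadrature, 21 nodes per
  dimension by default, centred and scaled by the current `(μ, Σ)`
  through the Cholesky factor. Per-study mode adaptation was judged
  unnecessary at typical diagnostic-study sizes (hundreds to tens of
  thousands of subjects); with 21² nodes the integrand is resolved far
  past the accuracy of the data. No continuity correction is needed on
  this path; it starts from the REML solution.
* **`method = "ml"`** is the same normal–normal model under full ML. It
  exists so that meta-regression can use likelihood-ratio tests: REML
  likelihoods are not comparable across fixed-effect structures.

### Pooled summaries, LRs, sROC

`summarize_bivariate()` back-transforms `μ` with Wald intervals on the
logit scale. Pooled likelihood ratios are *plug-in* functions of the
pooled sensitivity and specificity — `LR+ = p_s/(1−p_e)`,
`LR− = (1−p_s)/p_e` — with delta-method intervals on the log-LR scale
using the GLS covariance of `μ` (the bivariate-model LR pooling in the
style of Zwinderman & Bossuyt). Whether pooled LRs should be plug-in
functions or posterior means of study-level LRs is genuinely open;
plug-in is the default because it is what reproduces the published
posttest probability (0.0041 from pretest 0.01 at pooled sens 0.76 /
spec 0.59), and a parametric bootstrap (`ci = "bootstrap"`, ≥ 2000
draws) is available as a cross-check.

`sroc_curve()` maps the bivariate parameters to the Rutter–Gatsonis
HSROC curve via the Harbord correspondence. In logit space the curve is
the straight line through the summary point with slope `τ_s/τ_e`
(equivalently, HSROC shape `β = log(τ²_e/τ²_s)/2`); the between-study
correlation does not enter this curve — it would in a regression-based
alternative, which we did not adopt. AUC is trapezoidal over the full
FPR range on a uniform grid (default 1001 points; the tests show
stability to 1e-4 beyond 1000 points against an adaptive quadrature
oracle). Study-size weighting affects only plotted point sizes in
`autoplot()`, never the fitted curve.

### Proportion pooling, heterogeneity, meta-regression, Deeks, Fagan

* `pool_proportion()`: logit-scale DerSimonian–Laird, 0.5/1 correction
  for zero or all-event studies, Wald interval back-transformed; I² from
  the fixed-effect Q. A single study collapses to its Wilson interval;
  all-zero events return 0 with a one-sided exact upper bound, flagged.
* `heterogeneity()`: Cochran's Q under inverse-variance weights,
  `I² = max(0, (Q−df)/Q)`. For the bivariate fit, heterogeneity is
  assessed per outcome with this univariate statistic — the exact I²
  convention of the legacy software the literature used is not
  published, and the per-outcome Q is the defensible reading.
* `meta_regression()`: cell-means indicators for a categorical covariate
  on both pooled means, fitted by ML. Per-outcome p-values come from
  LRTs of "covariate on that outcome's mean only" against the
  covariate-free fit (`χ²` with `k−1` df); heterogeneity explained per
  outcome is `(τ²_null − τ²_cov)/τ²_null` from the fit with the
  covariate on both means, clipped to `[0, 1]`. Singleton categories are
  dropped with a warning.
* `deeks_test()`: WLS of ln DOR on `1/sqrt(ESS)` with weights ESS,
  where `ESS = 4·n₁·n₂/(n₁+n₂)` uses the corrected margins (so
  zero-case studies remain usable); two-sided t-test on the slope. If
  every study has the same ESS the funnel has no width: the slope is
  exactly 0 and the p-value `NA`.
* `fagan_posttest()`: odds-form Bayes; strictly increasing in both
  arguments, boundary pretest probabilities rejected.

## What the generators emulate — and what they do not

`simulate_cohort()` draws, per episode: case status
(`prevalence = 0.0025`, about 1 cancer per 400 first-round episodes, as
in the motivating programme); the nine questionnaire items at marginal
rates `(0.010, 0.015, 0.020, 0.075×6)` with item odds multiplied by
`ra_case_enrichment = 1.8` among cases (RA positivity ≈ 11% overall,
≈ 22% among cases); two FIT specimens with per-specimen sensitivity
0.57 and specificity 0.91 and a latent-sharing correlation of 0.47 (with
probability 0.47 both specimens copy a single Bernoulli draw — a
bleeding lesion tends to shed in both — which puts the 2-specimen union
sensitivity near 0.70); and a diagnosis lag whose band depends on the
programme's own parallel rule and on colonoscopy adherence (0.6):
positive adherent cases land in ≤ 90 days, positive non-adherent cases
in 91–365 days, negative cases in ≤ 365 days by default, all uniform
within the band. Every default is anchored to the corresponding
published margin and was fixed once, up front. RA positivity is always
produced by passing simulated *items* through `assess_risk()`, so the
rule is exercised end to end.

The generator does **not** emulate: age/sex structure, multi-wave
participation dynamics and within-subject correlation across waves,
quantitative hemoglobin concentrations (so no cutoff analyses on the
cohort side), clustered screening sites, or behavioural adherence that
depends on the test pattern. Passing tests therefore show that the
*pipeline arithmetic and the estimators* are right under the stated
model, not that the model captures every feature of a real programme.

`simulate_study_set()` draws study-level true accuracies from the exact
bivariate logit-normal the pooling stage assumes (log-uniform sizes,
uniform prevalences, binomial cells, optional planted covariate shifts).
That circularity is intentional — it is what makes "the fitter recovers
the generator's parameters" a meaningful check — but it also means the
simulations cannot detect model misspecification.

Reproducibility: both generators take an explicit integer seed, use R's
default Mersenne–Twister stream, and restore the caller's RNG state, so
the same parameters always give the same data on any platform running
the same R series.

## Problem sizes and test design

The unit tests run cohorts of 2×10⁵–3×10⁵ episodes (law-of-large-numbers
margins at 3–4 Monte-Carlo SEs), REML recovery at 120 studies, an
exact-binomial/normal agreement check at 25 large studies, and
cross-checks against `metafor` at 30–60 studies. The acceptance checks
use 200 studies for parameter recovery (every parameter within 2
standard errors of truth, and exact agreement with closed-form
inverse-variance pooling when `τ` is fixed at 0) and 500 replicates of
30 studies for Deeks' null calibration (rejection rate at α = 0.05
within 0.05 ± 0.03; the mean slope is judged against the slope's own
sampling spread, since the small-sample bias of ln DOR induces a
slight positive offset that is an order of magnitude below that
spread). These sizes were chosen to make Monte-Carlo noise small
relative to the tolerances while keeping the default suite quick to
run.

## Known limitations

* The published multi-time breakdown is internally inconsistent (its
  pattern rows imply 2214 positive cases, its aggregate row 2244); the
  fixtures ship both, `shanghai_confusion()` uses the aggregate row for
  the parallel strategy and the self-consistent breakdown for the rest,
  and the discrepancy is surfaced in the documentation rather than
  silently reconciled.
* Pooled estimates from the literature's own 103 studies are not
  reproducible here because the per-study 2×2 tables are not packaged;
  the pooled operating point is instead covered by simulation recovery
  at that operating point.
* The normal-approximation REML fit inherits the usual small-count
  downward bias of empirical logits; the exact-binomial path avoids it
  at higher cost.
* Repeat participants violate the independence the CIs assume; no
  cluster adjustment is attempted (a documented non-goal).
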
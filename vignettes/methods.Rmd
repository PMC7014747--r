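---
title: "Models and methods behind debulkr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind debulkr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(debulkr)
```

`debulkr` packages a preoperative decision problem from gynecologic
oncology: given serum HE4 and CA125 and routine clinicopathological
covariates measured before primary debulking surgery, predict whether a
patient with advanced (FIGO III–IV) epithelial ovarian cancer will end up
with residual disease — *suboptimal* cytoreduction, the positive class
everywhere in this package. This vignette explains the models, the
synthetic-data generator, and the design choices that were genuinely open.

## Diagnostic metrics and ROC machinery

All classification accuracy flows through a 2×2 confusion table with
suboptimal as the positive class. Sensitivity, specificity, PPV, NPV and
accuracy follow their standard definitions; a metric whose denominator is
empty (e.g. PPV when nothing is flagged) is reported as `NA`, never as a
coerced 0/0. Two identities are enforced by tests on arbitrary tables:
`accuracy = (tp+tn)/n` exactly, and
`accuracy = prev·sens + (1−prev)·spec`.

The ROC curve is the empirical one, with operating points at every
distinct score under the rule *score ≥ threshold flags suboptimal*. The
AUC is the midrank Mann–Whitney statistic, so ties between a positive and
a negative score count 1/2. The trapezoidal area under the curve polygon
must equal the midrank AUC to 1e-12; the suite checks this dual-route
identity on randomized inputs, and cross-checks the AUC against pROC. AUC
is invariant under strictly increasing score transforms, and the Youden
cutoff maps through such transforms — also property-tested.

**Cutoff selection.** Marker cutoffs maximize Youden's
J = sensitivity + specificity − 1 over candidate cutoffs placed at
midpoints between consecutive distinct scores (± infinite sentinels). Ties
break toward the lowest cutoff, i.e. toward sensitivity, which is the
clinically conservative direction for a triage marker. The selection
criterion used for the originally published cutoffs (777.10 pmol/L HE4,
313.60 U/ml CA125) is not recorded; Youden is the conventional default and
is what the package assumes.

**Uncertainty and power.** AUC standard errors use the Hanley–McNeil
closed form with `Q1 = A/(2−A)`, `Q2 = 2A²/(1+A)`; confidence intervals
are symmetric normal, clipped to [0, 1]. DeLong variances are deliberately
not implemented. Power against the null AUC 0.5 embeds the one-sided
rejection region of a two-sided α test:
`power = Φ((A₁ − 0.5 − z₁₋α/₂·SE₀)/SE₁)`. At A₁ = 0.73 with 31 positives
and 52 negatives this gives 0.955, i.e. the 96% figure for the 83-patient
design; the formula's monotonicity in A₁ and in both group sizes is
property-tested.

## The PIV score

Each of the eight parameters is dichotomized into a risk indicator:
age > 68.5 y, FIGO IV, non-serous histology, grade 3, CA125 ≥ 313.60,
HE4 ≥ 777.10, ECOG > 0, ASA ≥ 3. Boundary conventions are deliberate:
markers and ASA use a closed `≥` (a patient at exactly the cutoff is
flagged), while age and ECOG use strict `>` because their cutoffs sit
between attainable values. The non-serous direction for histology is
reverse-engineered from the published per-parameter table (8/31
non-serous among suboptimal gives the printed sensitivity 0.26; 45/52
serous among optimal gives specificity 0.87), even though the published
multivariable fit points the other way; for the PIV pathway the
diagnostics table wins.

The published construction sentence (include parameters with accuracy
≥ 75%, PPV ≥ 50% and NPV ≥ 50%, one point each) is internally
inconsistent: no parameter reaches accuracy 0.75 in the same table, the
printed point column contains 2s, and the stated 0–8 score range is
incompatible with eight one-point parameters that the threshold table
nevertheless sweeps to ≥ 8. The package therefore ships two explicit
weighting modes and forces neither:

- `ppv_weighted` (default): all parameters included, 2 points when
  PPV ≥ 0.5, else 1. This reproduces the printed point column
  (2,1,2,1,1,2,2,1) exactly, with a theoretical maximum of 12.
- `selected_only`: only parameters passing the PPV and NPV thresholds
  (accuracy threshold exposed as `accuracy_min`, defaulting to 0 because
  the printed 75% excludes everything), each at 2 points; on the published
  metrics this selects age, histology, HE4 and ECOG and yields the 0–8
  range.

The threshold sweep evaluates `PIV ≥ t` for t = 1..max score.
Sensitivity is non-increasing and specificity non-decreasing in t by
construction; the implementation still verifies this as a post-condition
and the suite quantifies it over random cohorts.

## The logistic pathway

Covariates enter as continuous age (years) plus indicators for
CA125 ≥ 313.60, HE4 ≥ 777.10 and serous histology; the outcome is coded
suboptimal = 1. Fitting is plain Newton/IRLS on the Bernoulli
log-likelihood: convergence when the maximum absolute score drops below
1e-8 (50 iterations cap), Wald standard errors from the inverse observed
information, 95% Wald intervals on the odds-ratio scale. The
log-likelihood trace is retained and must be non-decreasing. Complete or
quasi-complete separation is an explicit error — detected via diverging
coefficients during iteration or fitted probabilities within 1e-8 of 0/1
at convergence — because a silently divergent fit is worse than no fit;
no penalized fallback is offered. `glm()` serves as an independent oracle
in the tests, never as the implementation.

The split into training and validation sets is a simple seeded random
partition with `round(n·fraction)` (half-up) training rows — fraction
43/83 reproduces a 43/40 split of an 83-patient cohort; stratification by
outcome is available but off by default since the original split was
described only as random. Calibration uses the Hosmer–Lemeshow
deciles-of-risk statistic (quantile groups with ties kept together,
df = groups − 2); its type-I error under a correctly specified model is
only approximately nominal, and the suite checks it stays within ±0.03 of
0.05 over 500 simulated replicates. Validation reports the midrank AUC
with Hanley–McNeil CI and the operating point at the Youden-optimal
probability cutoff.

The originally published coefficient vector
(`0.12·age − 2.38·ca125_high − 1.86·he4_high − 2.74·serous − 3.37`) is
stored verbatim and applied as a fixed scorer. Its sign conventions are
internally inconsistent in the source (the continuous age odds ratio 1.13
implies the 0.12 per-year coefficient, but the indicator signs conflict
with the univariate directions and with the group frequencies), and the
text never states whether "p" is the probability of optimal or suboptimal
surgery — so the package exposes the raw linear predictor and its
inverse-logit without reinterpreting signs, and parameter-recovery tests
treat the vector purely as a known generating truth.

## The synthetic cohort generator

Patient-level data for the original cohort were never deposited, so the
generator stands in for them. It emulates the published characteristics
table: outcome Bernoulli(31/83); age Gaussian per outcome group
(52.13 ± 9.81 optimal, 56.45 ± 11.24 suboptimal), truncated to [18, 90]
by resampling (at these parameters the truncation shifts the mean by
under 0.1%); CA125 and HE4 log-normal per group with parameters
moment-matched so the natural-scale mean and SD are exact
(`sdlog² = ln(1 + (sd/mean)²)`, `meanlog = ln(mean) − sdlog²/2`) — a
log-normal is the natural choice for positive markers whose SD rivals
their mean, which a Gaussian cannot accommodate; and categorical
frequencies read off the table (the pooled grade 1–2 row is split evenly
between grades 1 and 2, a choice that affects nothing downstream because
only grade 3 enters any model). A single RNG stream draws records in
order; the seed is recorded in the cohort's provenance attribute. For
worked examples that condition on the observed 52/31 outcome split, the
group sizes can be fixed exactly via `outcome_counts`.

What the generator does *not* emulate: within-group covariate dependence
(the source reports no covariance structure, so covariates are
conditionally independent given outcome — this makes the synthetic
prediction problem somewhat easier than the real one), distributional
shape beyond the first two moments, and any data-dependent published
estimate. Consequently the published cutoffs, marker AUCs (0.68/0.53),
fitted odds ratios and the validation AUC 0.71 are *not* reproduction
targets on synthetic data; tests cover them qualitatively (signal
direction, monotonicity) while the desk-scale arithmetic facts — the
62.65% optimal rate, the PIV ≥ 6 confusion arithmetic, the 96% power,
the point column, the generator's own calibration — are reproduced
exactly or within Monte-Carlo tolerance.

Calibration checks run at n = 200,000, where the grand mean age
(prevalence-weighted mixture of 52.13 and 56.45 → 53.75) and the overall
marker means (CA125 → 1260.84, HE4 → 635.65) are recovered within 2%;
unit tests use smaller cohorts (60,000 and below) to keep the default
suite fast.

## Numerical and interface choices

- Sample SDs use the n−1 denominator everywhere.
- Group comparisons: Welch's t by default — applied to the published HE4
  group moments it reproduces the printed p = 0.006 — with the pooled
  test as an option; Pearson chi-square without continuity correction
  (the printed FIGO p-value 0.791 differs from textbook Pearson's 0.793
  by more than rounding; the original software's exact variant is
  unknowable, so equality is not forced), warning when any expected cell
  is below 5.
- The published per-parameter table prints its PPV and NPV columns
  transposed relative to the standard definitions (specificity 100% with
  PPV below 100% is arithmetically impossible); the package keeps the
  standard definitions, under which the PIV ≥ 6 row reads sensitivity
  0.226, specificity 1.00, PPV 1.00, NPV 0.684, accuracy 0.711.
- Report serialization uses fixed 4-decimal formatting and stable
  ordering, so re-rendering a bundle is byte-identical; the pipeline's
  top-level seed expands into fixed-offset sub-seeds for generation and
  splitting so stages are independently reproducible.
- The pipeline is driven from R (`run_full_analysis()` /
  `render_reports()`); there is no shell entry point, as the package's
  audience works in R.

## Known limitations

The generator's conditional-independence assumption understates the real
cohort's structure; single-peak PIV histograms and the qualitative
score–outcome gradient carry over, exact frequencies do not. The
Hosmer–Lemeshow statistic's chi-square reference is approximate at n ≈ 40
training sets. Hanley–McNeil standard errors are slightly conservative
for continuous scores with many ties. None of the data-dependent
published estimates can be validated without the original patient data.
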
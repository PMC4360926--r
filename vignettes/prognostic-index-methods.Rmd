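---
title: "Methods: deriving and validating an admission vital-signs prognostic index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: deriving and validating an admission vital-signs prognostic index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vitalindex)
```

## The clinical problem and the model

Among patients hospitalized with sepsis, admission vital signs carry
prognostic information that bedside staff can collect without
laboratories or monitors. The package implements a
reduced-segmentation prognostic index: each of five admission variables
contributes one point when deranged — respiratory rate ≥ 30
cycles/minute, pulse ≥ 100 beats/minute, mean arterial pressure (MAP,
computed as (SBP + 2·DBP)/3) ≥ 110 or < 70 mmHg, axillary temperature
≥ 38.6 or < 35.6 °C, and Glasgow coma score ≤ 14 — for a maximum of 5.
Its comparator is the Modified Early Warning Score (MEWS), a
multi-band score with maximum 14 under the banding used here.

Index performance is summarized by dichotomizing the score (≥ 3 versus
0–2 for the proposed index) and estimating the unadjusted odds ratio of
in-hospital death with the Woolf (log-odds Wald) method:
OR = ad/bc, CI = exp(ln OR ± z·√(1/a + 1/b + 1/c + 1/d)), and a
two-sided normal p-value for ln OR/SE. The Woolf estimator is used
because it reproduces the published confidence intervals and p-values
exactly at display precision; it also coincides with the
maximum-likelihood logistic-regression coefficient for a single binary
predictor, which the test suite verifies to 10⁻⁶.

Per-score mortality tables are the only patient-level information
available from the published cohorts, so per-patient (score, outcome)
records are rebuilt from them: a row with *n* patients and a printed
mortality percentage *p* contributes round(n·p/100) deaths, rounding
half away from zero. This reconstruction reproduces both published
overall mortality figures (23% development, 30% validation) and all
published odds-ratio statistics exactly.

## The derivation procedure

The index cutoffs are derived from a development cohort in three steps.

**Risk curves.** For each continuous vital sign a univariable logistic
model of in-hospital death is fitted by maximum likelihood on a
restricted cubic spline basis (truncated-power natural spline,
`rcs_basis()`; linear beyond the boundary knots, nonlinear terms
normalized by the squared knot span). Predictions are evaluated on a
grid at the variable's measurement resolution (1 cycle/min, 1 beat/min,
1 mmHg, 0.1 °C).

**Categories.** Grid runs where the predicted death probability exceeds
the cohort's average mortality become *prognostic* intervals; the
complementary runs — at or about the average — are *reference*. Each
category is annotated with the observed (not predicted) mortality of
the records inside it.

**Cutoffs.** The boundaries of the prognostic intervals, which lie on
the measurement grid, become the scored bands of a derived index (one
point inside prognostic ranges). GCS is handled categorically
(≤ 12, 13–14, 15), not splined: the component collapses to a binary
"altered mental state" cutoff (≤ 14) when the lower categories show
above-average mortality.

### Numerical and design choices

* **Knots.** Default 7 knots, *equally spaced* across the central 99% of
  observed values, rather than the conventional quantile placement.
  Admission vitals are strongly right-skewed; quantile knots concentrate
  where data are dense and leave one long spline segment across the
  sparse upper range of blood-pressure-like variables — exactly where
  prognostic cutoffs (e.g. MAP ≥ 110) live. Equal spacing keeps
  curvature available there. A two-stage refinement then inserts two
  extra knots around each of the two steepest sections of the
  first-pass curve, so sharp risk transitions are tracked without
  spending degrees of freedom everywhere. Both choices are configurable
  (`k`, `knots`, `refine`).
* **Grid span.** The evaluation grid covers the 0.5th–99.5th percentile
  of observed values. Spline predictions beyond that rest on a handful
  of records and are extrapolations of the linear tails; categorizing
  them produced spurious boundary artifacts. Records in the trimmed
  tails are still assigned to the outermost categories.
* **Threshold.** Prognostic means *above the sample-average mortality*,
  with an optional tolerance (`tol`, default 0) for "about average".
  The default is exact: with admission pulse distributions whose median
  exceeds the pulse cutoff, a marginal risk curve that averages to the
  cohort mortality cannot cross any materially higher threshold at a
  clinically sensible cutoff, so a positive tolerance makes
  high-prevalence cutoffs undiscoverable in principle.
* **Association screen.** Before segmentation, each vital must show
  evidence of association with death: a likelihood-ratio test of the
  spline model against the intercept-only model at α = 0.01 (roughly a
  Bonferroni share of 0.05 across the four splined vitals). Without the
  screen, the fitted curve of a truly uninformative vital wanders above
  and below the average by sampling noise alone and every wiggle would
  be read as a prognostic range. The categorical GCS component is
  screened the same way with Fisher's exact test.
* **Boundary placement.** Category boundaries interpolate the exact
  crossing of the fitted curve with the threshold inside the bracketing
  grid cell, then snap to the nearest grid value; taking the first grid
  point above the threshold instead would bias every rising-side cutoff
  upward by up to one resolution unit. Runs shorter than `min_run`
  (default 3) grid steps are absorbed into their neighbours so
  single-point flickers do not fragment the categories.
* **Degenerate inputs.** Cohorts under 50 complete records, single-class
  outcomes, and non-convergent fits (separation) are refused with
  informative errors; curves entirely below the threshold yield a
  single flagged reference category and the variable is excluded from
  the derived index.

## The synthetic cohort generator

No patient-level data are deposited, so the generator emulates the
published study conditions and provides ground truth for testing the
derivation pipeline.

**Marginals** are calibrated to the published development-cohort
medians and interquartile ranges: log-normal for pulse (median 108),
respiratory rate (28), white cells (4.7), platelets (160), and age
(38); normal for axillary temperature (37.0 ± 1.33); GCS categorical
with 80% at 15, 14% at 13–14, 6% at ≤ 12 (≈ 20% altered mental state,
matching the published 21%). Spread parameters are IQR-matched
(`sdlog = log(q3/q1)/(2·z₀.₇₅)`). Systolic and diastolic pressure are a
correlated log-normal pair (log-scale correlation 0.6, spread 1.2× the
IQR-implied value, draws with DBP ≥ SBP rejected): the log-normal right
tail reproduces both the published MAP interquartile range (63–87 mmHg)
and the published prevalence of the upper prognostic MAP category
(≥ 110 mmHg, ~8% of the development cohort), which a normal pair
understates by an order of magnitude.

**Risk model.** Death is Bernoulli with logit risk built from one
smooth saturating sigmoid per abnormal direction,
`cap · plogis((x − center)/width)`: risk is flat across a reference
valley, rises smoothly, and plateaus at extreme derangement (risk
saturation, consistent with curves that "taper off" at high pulse
rates). Altered mental state adds log(2.4) to the log-odds (the
published unadjusted GCS ≤ 14 odds ratio). The intercept is calibrated
by bisection at generation time so expected mortality hits the target
(default 23%) within 0.5 percentage points.

**Planted cutoffs.** The sigmoid centers were solved once by Monte
Carlo (400,000 records) so that each vital's *true marginal risk curve*
crosses the categorization threshold exactly at the published cutoffs:
respiratory rate 30, pulse 100, MAP 70 and 110, temperature 35.6 and
38.6. Widths and caps were chosen for clinical plausibility and so the
crossings are steep enough to be localizable from n = 5000 cohorts;
they are frozen as package defaults and reported by
`planted_cutoffs()`. Smooth sigmoids (rather than piecewise-linear
hinges or global quadratics) were chosen for two measured reasons:
unbounded terms admit no joint calibration with all six crossings at
the published cutoffs, and kinked shapes bias spline-based crossing
estimates by cutting corners.

**What the generator does not emulate.** Vitals are drawn independently
(only marginals and risk shapes are matched — the true joint dependence
of admission vitals is unknowable from published summaries), there are
no missing values, no repeated measurements, and no site or treatment
structure. Passing recovery tests therefore show that the pipeline can
find cutoffs of this strength at this sample size under clean
conditions; they do not certify performance on small, collinear, or
incomplete real cohorts — the published cohorts themselves (n = 167 and
150) are an order of magnitude smaller than the simulated ones, and at
that size the curve estimates are far noisier.

## Test design and problem sizes

The suite checks reconstruction of every published statistic at display
precision; estimator-oracle agreement (Woolf vs `glm`) on 200 random
tables; spline correctness properties (linear tails, nested-model
agreement with a plain logistic fit, no spurious nonlinearity at
χ²-sized deviance gaps); cutoff recovery — each planted cutoff within
±2 resolution units of the nearest derived boundary in ≥ 90% of 20
cohorts of n = 5000; null safety — no prognostic interval on ≥ 90% of
20 null-risk cohorts; and generator calibration at n = 10,000 (medians
within 5%, realized mortality within 2 points). Cohort sizes were
chosen so the whole suite runs in well under a minute; design-time
validation used 60-seed batches, where per-cutoff recovery rates were
95–100%. The weakest cutoffs are the MAP pair (sparse tails; ±2 mmHg ≈
1.4 standard errors of the crossing estimate), so individual 20-seed
batches can dip to 80–85% for one cutoff by sampling variation.

## Known limitations

* The MEWS banding follows the comparator enumeration used in the
  source study; the original MEWS publication scores some ranges
  (e.g. pulse < 40) differently. The anomaly is annotated on the
  component rather than silently corrected.
* Printed integer bands share boundaries (SBP 80, SBP 100); shared
  boundaries are assigned to the higher-severity band.
* Derivation assumes univariable risk curves per vital; confounding
  between vitals is not modelled, matching the source procedure but
  limiting causal interpretation.
* Complete-case analysis only; the development study imputed missing
  respiratory rates, white cells, and GCS before analysis, which this
  package deliberately does not reproduce.
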
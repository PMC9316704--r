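---
title: "Assessing the constancy assumption: models, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing the constancy assumption: models, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(constancer)
```

## The question

A noninferiority margin built by the putative-placebo route borrows the
active control's effect over placebo from a historical meta-analysis. The
constancy assumption says that effect would reappear, unchanged, if the
control were tested against placebo today. `constancer` treats a corpus of
placebo-controlled meta-analyses as the unit of evidence about that
assumption: within each meta-analysis, the most recent trial(s) play the
role of "the future trial", and the remaining trials play the role of "the
historical evidence". If constancy held, the most recent trial's effect
would be an unbiased one-to-one reflection of the historical pooled effect.

## Effect harmonization

Trials arrive as per-arm summaries. Continuous outcomes become Cohen's
$d$ with the pooled SD; by default the Hedges small-sample factor
$J = 1 - 3/(4\,\mathrm{df} - 1)$ is applied, since small trials are common
in such corpora (the correction is a flag, `hedges`). The sampling variance
is $(n_a + n_p)/(n_a n_p) + d^2 / (2 (n_a + n_p))$.

Binary outcomes — whatever effect measure the original review declared
(risk ratio, odds ratio, risk difference) — are recomputed from the 2x2
table through one consistent route, the log odds ratio mapping
$d = \ln(\mathrm{OR})\,\sqrt{3}/\pi$ with
$\mathrm{Var}(d) = \mathrm{Var}(\ln \mathrm{OR}) \cdot 3/\pi^2$. A single
route exact in the arm counts beats re-deriving each declared measure, and
the mapping is invertible, which the tests exploit
($\exp(d\,\pi/\sqrt{3})$ must return the odds ratio to $10^{-10}$). Tables
with a zero cell get 0.5 added to all four cells of that table only; exact
tables stay exact.

Reviews measure both beneficial outcomes (healing) and harmful ones
(death, pain), so every estimate is oriented to a benefit-positive scale
before any pooling or correlation: harm-direction SMDs and CI bounds are
negated (and bounds swapped). The *arm responses* whose time trends are
examined separately — the placebo and active arm mean or event
proportion — deliberately stay on the raw outcome scale: they are read as
"what did the placebo arm experience", not as an effect. Whether a
published analysis of this kind used raw arm responses, standardized ones
or change scores is generally not stated; raw arm summaries are the only
quantity available in this data model, and that choice is fixed here.

## Recency split and pooling

Publication year is the only time resolution available, so "the most recent
trial(s)" means every trial tied at the review's maximum year; ties form a
joint last set (`k_last` may exceed 1), and a review whose trials all share
one year has no defined split and is excluded with an error. Eligibility
for the constancy regression requires at least 4 trials with at least 3
left after deleting the last set, reducing the chance that an extreme
single-trial SMD anchors either side of the regression. Ineligible reviews
are flagged and filtered at the regression stage, never silently dropped.

Pooling is inverse-variance with either a common-effect model or
DerSimonian–Laird random effects
($\tau^2 = \max(0, (Q - \mathrm{df})/C)$, $C = \sum w - \sum w^2 / \sum w$,
$I^2 = \max(0,(Q-\mathrm{df})/Q) \cdot 100$). The random-effects model is
the default, matching systematic-review convention; the choice is exposed
because the original analysis's pooling model is typically unstated. With
one trial both models return that trial's estimate; with $Q \le
\mathrm{df}$, DL collapses to the fixed model exactly. The pooling math is
implemented directly from these formulas (it is part of the method under
test) and the test suite cross-checks it against `metafor` as an
independent implementation.

Two year spans are computed per review: over all trials and over the
historical set only. The historical-set span is the regression default
(the covariate is meant to describe the historical evidence the prediction
is based on); both are stored.

## Trend analysis

Per review, Pearson and Spearman correlations of publication year with the
harmonized SMD, the raw arm responses, and total sample size. A minimum of
3 trials and 2 distinct years is required — two-point correlations are
always $\pm 1$ and would distort the category counts. A constant series has
no defined correlation; such reviews are excluded from that variable's
denominators and counted.

Strength bands on $|r|$: weak $< 0.3$, moderate $0.3 \le |r| \le 0.5$,
strong $> 0.5$. The conventional band edges overlap at 0.3 and 0.5; here
both boundary values are assigned to "moderate" so every coefficient has
exactly one class, and "strong" is reserved for strictly more than 0.5.
$r = 0$ is classed weak-positive by convention.

Corpus aggregation reports, per variable: percent negative, median, mean
with a t-based 95% CI across reviews. The CI is on plain correlation
coefficients (no Fisher z), because the summaries being emulated are plain
means of $r$; a `fisher_z` flag provides the transformed variant.

## The constancy regression

Across eligible reviews,
$$\mathrm{SMD}_{lt} = \beta_0 + \beta_1\,\mathrm{SMD}_{dl} +
\beta_2\,\text{(year difference)} + \beta_3\,\text{(year of last trial)} +
\varepsilon,$$
fitted by weighted least squares with weights equal to the historical
meta-analysis's total sample size, as supplied (WLS estimates are invariant
to weight rescaling, which the tests verify). Calendar year enters
uncentered by default so the intercept is comparable to published fits of
this form; a centering flag changes only the intercept. Standard errors
come from the weighted coefficient covariance and CIs use the t multiplier
on $n - p - 1$ df.

Stepwise selection is the forward-entry $p < 0.05$ / backward-removal
$p > 0.10$ flavor — the common default of the statistical packages used for
such analyses — made deterministic: candidates are only the two year
covariates, the best (smallest-p) candidate enters first, ties break on
candidate order, and $\mathrm{SMD}_{dl}$ is forced into the model because
the scientific question is its slope. Degenerate fits (zero residual df)
have undefined p-values, which selection treats as non-significant.

The headline quantity is the attenuation $1 - \beta_1$. A slope of 0.88
means a future trial is expected to show an effect 12% smaller than the
historical meta-analysis predicts, and an NI margin derived from that
meta-analysis deserves at least that discount. Prediction for a future
trial adds the coefficient covariance at the query point to the residual
variance scaled by the future trial's implied weight; no weight is knowable
for a trial not yet run, so the fitted corpus's median weight is the
default, overridable.

Rank-deficient designs abort with the collinear columns named; a saturated
fit (rows equal to parameters) is allowed — it reproduces the data exactly
with undefined uncertainty — because the fitting contract is defined by the
normal equations, not by the availability of residual df.

## What the generator emulates

`sim_config()` defaults describe a realistic corpus of placebo-controlled
meta-analyses, frozen once:

* **236 reviews**, trials per review $4 + \mathrm{NB}(\mathrm{size}=0.55,
  \mu=5.9)$ — median 7, mean 9.9, expected maximum ≈ 51 at 236 reviews.
* **Years 1931–2016**; each review's trials fall in a window of
  exponential width (mean 20 years, minimum 1), placed uniformly, so most
  reviews span one or two decades while a few span most of the era
  (realized spans ~1–80 years).
* **Outcome mix**: 68% binary, 65.4% harm-direction, review-level.
* **Sample sizes**: per-arm lognormal with a review-level size factor
  (sd 0.65 on the log scale) and trial-level spread (sd 0.35), baseline
  median arm ≈ 70, growing by 0.2% per year. The review-level factor is
  essential: review totals in real corpora span two orders of magnitude
  (roughly 100 to 40,000 participants, median near 1,200), which no
  trial-level-only model reproduces, and it is what makes historical
  sample size an informative regression weight.
* **Effects**: review base effect $\theta_j \sim N(0.3, 0.3^2)$,
  between-trial heterogeneity $\tau = 0.15$ (typical of SMD
  meta-analyses), and a linear drift `effect_drift` in SMD units per year
  (default 0 — the constancy null — so departures are always explicit).
  `placebo_drift` moves the placebo response: raw units per year for
  continuous outcomes (unit outcome SD), logit units per year for binary.

Continuous outcomes draw arm means from their exact normal sampling
distribution and arm SDs from the scaled chi-square, so the implied SMD is
centered on the trial's true effect with the correct sampling variance.
Binary outcomes drift the placebo probability on the logit scale and set
the active arm's log odds ratio to $d\,\pi/\sqrt{3}$, making the true SMD
under the package's own conversion exact by construction. One root seed
spawns per-review child seeds, so a corpus is byte-reproducible and any
single review can be regenerated alone.

What the generator does **not** emulate — and therefore what passing tests
cannot certify about real corpora: publication bias and small-study
effects (real corpora are heavily enriched for significant results),
outcome-measure heterogeneity within a review, correlated multi-arm
trials, change-from-baseline outcomes, and any dependence of trial size on
interim evidence. Year of publication is the simulation's only time axis,
mirroring its use as a proxy for conduct year.

`simulate_regression_rows()` skips the trial level entirely: covariates
are drawn from stated distributions ($\mathrm{SMD}_{dl} \sim N(0.3, 0.3)$,
year difference $\sim U(1, 40)$, year $\sim U(1990, 2016)$, weights
lognormal with median 1160) and the response has noise variance
$\sigma^2\,\tilde w / w_i$, so sample-size weighting is the *correctly
specified* model. This mode is the right instrument for parameter-recovery
and calibration claims about the regression itself, separate from the
corpus model.

## Numerical and testing choices

Simulation sizes in the test suite were chosen to make Monte-Carlo error
small relative to the quantities asserted: 50 replicates of 5,000 rows for
coefficient recovery, 200 corpora of 200 reviews for null calibration, 50
corpora of 236 reviews for drift detection, 100–200 random instances for
oracle-equivalence checks at $10^{-8}$–$10^{-10}$. Oracles are coded
independently of the implementation (explicit loops over the pooling
formulas; a literal normal-equation solve for WLS).

## Known limitations

* **Regression dilution.** $\mathrm{SMD}_{dl}$ is itself an estimate; its
  measurement error biases $\beta_1$ toward zero, so the attenuation
  $1-\beta_1$ conflates true temporal drift with errors-in-variables
  shrinkage. The package reports the conflated quantity, as the design
  being emulated does; an errors-in-variables extension is out of scope.
* **Anti-conservative nominal tests under sample-size weighting.** The
  variance of $\mathrm{SMD}_{lt}$ is the last trial's sampling variance
  plus the heterogeneity floor $\tau^2$; it neither scales with the number
  of historical trials nor vanishes for huge reviews. Total historical
  sample size is therefore only roughly proportional to inverse error
  variance, and the model-based t-tests of the WLS fit over-reject under
  the constancy null on realistic corpora (the package's own calibration
  study measures roughly 11–14% at a nominal 5% when $\tau = 0.15$). The
  same tests are well calibrated when the weights are correctly specified
  (the regression-row generator). Conclusions about *which* covariates
  matter on a real corpus should lean on effect sizes and robustness
  checks, not on these nominal p-values alone.
* **Year ties and publication lag.** Year-of-publication resolution makes
  the "last set" a coarse object, and publication lag decouples it from
  conduct time in ways the pipeline cannot see.
* The six-category counts and corpus correlations depend on the per-review
  minimum of 3 trials; reviews failing it are excluded and counted, which
  a comparison against other tabulations must account for.
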
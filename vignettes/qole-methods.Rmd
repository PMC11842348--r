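---
title: "Methods: scoring, psychometrics, and meaningful-change thresholds for the QOL-E"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring, psychometrics, and meaningful-change thresholds for the QOL-E}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qolemwpc)
```

This vignette documents the models and rules the package implements, the
choices made where the methodology was genuinely open, and what the
synthetic-data generator does and does not emulate.

## Scoring model

The QOL-E comprises 29 items: Items 1–2 rate general well-being and never
enter a score; the remaining 27 form six domains (FIS, FUN, SOC, SEX, FAT,
MDSS). Each item response is oriented so higher = better (items worded as
symptoms or impacts are reversed), and a domain score is the answered
fraction of the domain's raw range, scaled to 0–100:

$$S_d = 100 \cdot \frac{\sum_{j \in \text{answered}} x_j^{\text{oriented}}}
{\sum_{j \in \text{answered}} (\text{max}_j - \text{min}_j)}.$$

This is affine in the oriented raw sum, with the worst response pattern at
0 and the best at 100. Summaries are means: GEN over the five non-MDSS
domains, ALL over GEN and MDSS, TOI over FIS, FUN and MDSS.

Three conventions had to be fixed where the instrument's public
documentation is silent:

* **Missing items.** A domain is scored when at least half its items are
  answered (`min_answered_fraction = 0.5`, the common convention for
  patient-reported outcome instruments); answered items are prorated over
  their own raw ranges, which reduces to mean-prorating when items share a
  range and generalizes it when they do not.
* **Missing SEX in summaries.** The sexual well-being domain is skipped
  frequently and performs weakly psychometrically; a missing SEX is
  dropped from GEN (mean of the remaining four domains). Any other missing
  constituent makes the summary missing.
* **Item-level map.** The per-item response scales live in the
  instrument's scoring sheet, which is distributed with the questionnaire
  rather than published. The default schema is therefore a documented
  reconstruction constrained to the instrument's known structure — 29
  items (2 general), per-domain total raw ranges 8 / 9 / 4 / 12 / 21 / 42
  — chosen so the minimum possible change per domain,
  $100 / \text{range}$, equals the published values
  {12.5, 11.1, 25.0, 4.8, 2.4} for the five triangulated domains. The SEX
  range of 12 (minimum change 8.3) is inferred from the granularity of
  published score quantiles (multiples of 100/12).
  The schema is configuration-driven (`qole_schema()`, `read_schema()`)
  so the official sheet can be swapped in without code changes.

## Psychometric analyses

**Distributional properties.** Ten-point bins $[0,10), \ldots, [90,100)$
with exactly 100 as its own category; floor/ceiling effects flagged when
strictly more than 15% of non-missing scores equal 0 or 100. Quartiles use
linear interpolation between order statistics (`quantile` type 7); the
source analyses never state a convention, and this is R's default.

**Validity.** Spearman correlations (average ranks for ties; two-sided P
from the $t$ approximation on $n-2$ df) pooled across baseline and
Week 24, so a patient contributes up to two observations. Magnitudes are
banded weak (< 0.3), moderate, strong (≥ 0.7), very strong (≥ 0.9).
Observed correlations are compared with a prespecified grid of expected
magnitude and sign; the original grid is not public, so the default
(`default_hypothesis_grid()`) encodes its stated logic — moderate against
QLQ-C30 global/functioning scales and the most related symptom scales,
weak against the other symptoms and all clinical outcomes, weak
everywhere for SEX — and ships as data, editable without touching the
verdict code. A non-significant (P > 0.05) wrong-sign correlation is
reported as *indeterminate* rather than *wrong sign*. Known-groups
comparisons report n/median/Q1/Q3 by baseline overall-health rating and
by baseline transfusion dependency (≥ 1 RBC unit in the prior 8 weeks);
interquartile intervals are treated as closed, so a shared endpoint
counts as overlap — the conservative reading.

**Reliability.** Test–retest ICC(A,1) (absolute agreement, single
measurement) from the two-way mean squares of an $n \times k$
subject-by-occasion matrix, computed on patients from the one trial with
a screening re-test whose overall-health rating was identical at both
occasions. Internal consistency: raw and standardized Cronbach alpha with
item-deleted values, and McDonald's omega from a one-factor fit to the
item correlation matrix by the minimum-residual criterion (sum of squared
off-diagonal residuals, BFGS with analytic gradient, relative tolerance
1e-8, at most 500 iterations, eigenvector start). Negative uniquenesses
(Heywood cases) are clipped at zero and flagged; non-convergence returns
a missing omega rather than a number. Listwise deletion is used at the
item-matrix level — the simplest defensible choice, with the retained n
reported. Omega needs at least three items, so the two-item domains
report alpha only.

## MWPC determination

Anchors are change measures patients understand directly: the
overall-health item (category change), the health-compared-to-a-month-ago
item (absolute follow-up score, since it measures change directly),
QLQ-C30 Items 29/30 (category change), hemoglobin change and RBC-unit
change. An anchor qualifies when |r| > 0.3 (strict) against the change in
every score except SEX. The hemoglobin (± 1.5 g/dL) and RBC-unit (± 2
units) category cut-points are configuration defaults, not published
values.

Patients are grouped by anchor change level; any group with n ≤ 10 merges
into its neighbour toward "no change", outermost first, repeating until
all groups exceed 10. Collapsing never crosses the no-change boundary: a
side that cannot reach 11 patients is kept whole and flagged rather than
silently absorbed — absorbing would contaminate the reference group.

The published analyses judge eCDF separation visually; the package
codifies it so it is deterministic and testable: the improvement (or
worsening) group separates from the no-change group when its eCDF lies
strictly on the correct side at ≥ 80% of the pooled grid points where the
curves are informative (not both 0 or both 1), *and* the median
between-group difference reaches the score's minimum possible change in
the correct direction.

Distribution-based estimates are computed on the screening-design trial
only: $\mathrm{SEM} = \mathrm{SD}_{\text{baseline}}\sqrt{1-\mathrm{ICC}}$
and $0.5 \cdot \mathrm{SD}_{\text{baseline}}$.

**Threshold rules.** Because a patient's score moves in discrete steps,
the proposed improvement threshold of a domain is the smallest achievable
change clearing the measurement-noise floor: with
$D = \max(\mathrm{SEM}, 0.5\,\mathrm{SD})$ and minimum possible change
$m$, the threshold is $\lfloor k^{*} m \rfloor$ for the smallest positive
integer $k^{*}$ with $k^{*} m \ge D - 0.5$. The half-point tolerance
absorbs the one-decimal rounding of reported inputs (without it, a
reported SEM of 12.6 would reject the physical domain's own step of
12.5). Summary scores move in steps too small to matter, so they share a
single practical threshold: the floor of the smallest primary-anchor mean
improvement among the three summaries, required to clear each one's
$D - 0.5$; if the smallest candidate fails that bound the next larger
candidate mean is used. Worsening thresholds are the negatives of the
improvement thresholds by construction. For each score the anchor-based
range is reported as $[\max(D, \text{min estimate}), \text{max
estimate}]$ per side over the mean and median changes of anchor sides
passing the eCDF check (an ineligible side contributes the open-ended
$[D, \infty)$), and a consistency flag records whether the threshold lies
within the improvement range widened by one point. Applied to the shipped
published inputs these rules reproduce the published thresholds for every
domain and the summaries; the ranges agree for fifteen of sixteen sides,
the one divergence (FUN worsening lower bound, 21.1 vs 21.6) arising
because the published table floors sub-noise estimates inconsistently
across rows.

## The synthetic cohort

No public patient-level data exist for the four source trials, so the
generator produces cohorts with the statistical structure the validation
assumes; its defaults are the study conditions, not tuning knobs.

* **Design**: 227/34/158/39 patients across four trials; baseline and
  Week 24 everywhere; a screening re-test only in the first
  (MEDALIST-like) trial; no QLQ-C30 in the fourth (RevMDS-like) trial.
* **Item model**: one latent trait per domain loading 0.6 on a shared
  general factor (0.2 for SEX, keeping its correlations weak), an
  occasion-level disturbance, and item noise (variance 0.15). Responses
  are graded cuts of the item latent; thresholds sit at the normal
  quantiles of configured level probabilities, so baseline marginals —
  domain means (lowest ≈ 47.5 for SOC, highest ≈ 74 for FAT), the SOC
  floor mass and the FUN/SOC/SEX ceiling mass — are controlled
  analytically rather than tuned.
* **Reliability calibration**: the occasion variance is solved from the
  target ICC with an analytic correction for categorization attenuation
  (the ordinal cut behaves like extra item noise of relative variance
  $(1-\lambda^2)/\lambda^2$, where $\lambda$ is the cut-vs-latent
  correlation computed from the thresholds). Setting a domain's target to
  1 switches off occasion and item noise entirely, making screening and
  baseline identical.
* **Change and anchors**: a Week 24 latent shift (SD 1.1 between-subject
  units, loading 0.9 on a shared change factor; 0.15 for SEX) plus small
  trial-specific drifts; anchors are noisy ordinal readouts of the shift,
  with readout strengths set so the overall-health item and QLQ-C30
  Item 29 fall in the 0.3–0.5 correlation band while the
  change-direct item, Item 30, hemoglobin and RBC-unit changes fall
  short on at least one score — the published selection pattern.
* **Clinical outcomes**: hemoglobin N(9.5, 1.9) g/dL weakly tied to the
  health factor; transfusion dependence with probability 0.683 (dependent
  patients draw 1 + Poisson(1.8) units); platelet counts log-normal with
  P(< 100), P(100–400), P(> 400) matching the published mix; block-wise
  missingness (e.g. 11.8% missing hemoglobin, 12% missing SEX items).
* **Determinism**: all draws flow from one root seed through named
  substreams (latent, items, anchors, clinical, missingness), so
  components are independently reproducible and identical seeds give
  byte-identical cohorts.

What the generator does **not** emulate: treatment arms and real
treatment effects, survival or progression, informative (non-random)
missingness, cross-trial differences in administration or translation,
and any true joint distribution of anchors and clinical outcomes — the
anchor parameters are calibration targets, not estimates. Tests passing
on this cohort therefore demonstrate that the estimators and rules are
correct and stable under the assumed structure, not that the instrument
performs identically on real trial data.

## Numerical choices and problem sizes

Scores are kept at full precision internally; rounding (one decimal for
scores and minimum possible change, two for correlations) happens at the
reporting layer. Degenerate inputs return missing values with warnings
rather than errors where the analysis can proceed (constant ICC
matrices, zero-variance items, sub-minimum correlation pairs), and
errors where it cannot (invalid responses, unknown items, empty anchor
sets).

The test suite sizes its simulations to what the properties need:
estimator-oracle equivalence uses 100 random small matrices (n 3–10,
k 2–4, tolerance 1e-10) and tie-heavy samples (tolerance 1e-12); ICC
recovery uses 200 single-trial cohorts of 227 patients at a target of
0.80 (± 0.10); omega recovery one sample of n = 5000 (± 0.03);
distributional calibration 20 default cohorts of 458; the end-to-end
anchor-estimate stability check compares 12 default cohorts against an
8000-patient reference. The full pipeline on the default cohort runs in
a few seconds on one CPU.

## Known limitations

The default schema is a reconstruction: per-item wording-based reversals
and any "prefer not to answer" option for the sexual domain are unknown,
so item-level outputs (e.g. alpha-if-deleted labels) are structural
placeholders until the official sheet is loaded. The eCDF separation and
threshold-selection rules are codifications of judgements made visually
and narratively in the source analyses; they reproduce its published
decisions but are one defensible formalization among several. ICC
confidence intervals and hierarchical omega variants are out of scope.
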
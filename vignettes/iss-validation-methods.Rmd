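---
title: "Methods: ischaemia severity scoring and its validation pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ischaemia severity scoring and its validation pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sewss)
```

## The scale

Diabetic foot wounds are graded on a four-point ischaemia severity scale
(ISS): 0 non-ischaemic, 1 mild, 2 moderate, 3 severe.  Four non-invasive
vascular tests can each place a patient on the scale:

* **Pedal pulse palpation** (per artery, dorsalis pedis and tibialis
  posterior): 0 bound strong pulse, 1 palpable but diminished, 2 thready and
  scarcely palpable, 3 non-palpable.  The package reconciles the two
  arteries by taking the worse (maximum) grade — a conservative choice the
  source material leaves open.
* **Ankle/brachial index (ABI)**, computed with the high-ankle-pressure
  convention: the larger of the two ankle systolic pressures divided by the
  maximum arm systolic pressure.  Bands: 0.9–1.2 normal, 0.7–0.89 mild,
  0.5–0.69 moderate, below 0.5 severe.  The published band edges leave the
  points between 0.89 and 0.9 (and 0.49/0.5) unassigned; we close the gaps
  with half-open intervals `[0.9, 1.2] / [0.7, 0.9) / [0.5, 0.7) / [0, 0.5)`
  so that every non-negative index is classified and the bands partition the
  axis — a property the test suite checks on a dense grid.
* **Toe/brachial index (TBI)**: hallux pressure over the maximum arm
  pressure; at or above 0.75 normal (ischaemia is defined by TBI < 0.75, so
  the boundary point is assigned to normal), 0.60–0.74 mild, 0.30–0.59
  moderate, below 0.30 severe.
* **Doppler waveform category**: triphasic 0, biphasic 1, monophasic 2,
  absent 3.  This mapping is asserted from the reported per-level waveform
  prevalences rather than stated as a rule, so it is configurable
  (`scoring_config(waveform_map = ...)`).

An ABI above 1.2 is treated as incompressible (Mönckeberg medial
calcification) and is *skipped*, not classified: the TBI is robust to
calcification and takes over.

When tests disagree, `resolve_iss()` takes the classification of the most
reliable available test.  The default precedence — waveform > TBI > ABI >
pulse — follows the escalating reputed accuracy of the tests; whether the
original study used waveform to reassign or merely confirm levels is
ambiguous, so the order is a config parameter rather than a constant.

The Saint Elian Wound Score System (SEWSS) sums ten factor subscores
(location, topographic aspects, affected zones, ischaemia, infection,
oedema, neuropathy, depth, area, healing phase), each 0–3, into a 0–30 sum
banded I (≤ 10), II (11–20), III (21–30).  Although the factor description
speaks of scores "from mild (1 point)", the ischaemia factor is explicitly
zero for non-ischaemic patients; we therefore allow 0 for any absent
aggravating factor, since otherwise an unremarkable wound could not be
represented.

## The synthetic cohort

No patient-level data accompany the scale, only per-level summary tables
(n = 235 split 159/24/25/27 across levels 0–3, means ± SD of the baselines
and indices, and outcome counts).  `generate_cohort()` draws a cohort whose
per-level distributions emulate those tables, so the whole downstream
pipeline is testable.  Design choices, in order of consequence:

* **Latent level first.** Each patient has a latent ISS level (exact counts
  159/24/25/27 by default, or multinomial).  All measurements are drawn
  conditionally on it and are conditionally independent — no joint
  distribution of the tests is published, so the only correlation between
  ABI, TBI, pulses and waveform within a patient is the one induced by the
  shared level.
* **Band concordance.** With probability `band_concordance` (default 0.95)
  an index draw is truncated to the band of the latent level; otherwise it
  comes from the level's unconstrained marginal.  This keeps the scored
  level in agreement with the latent level for well over 90% of records
  (checked by test) while leaving realistic cross-test discrepancies.  With
  the published SDs alone (e.g. TBI 0.90 ± 0.35 at level 0, a third of which
  lies below the 0.75 cut) an unconstrained generator would contradict the
  published near-diagonal relation between tests and level.
* **Pressures are derived, not drawn.** The published ankle/toe pressure
  summaries are mutually inconsistent with the published index summaries
  (severe-level ABI 0.47 times a normal arm pressure cannot average
  95 mmHg), so the generator treats the indices as primary and reconstructs
  pressures as index × max arm pressure (arms ~ N(130, 15²) mmHg truncated
  to 90–200).  `compute_abi()`/`compute_tbi()` then recover the generated
  indices exactly.  The toe pressure is missing with probability 0.119, the
  reported rate of unmeasurable toes.
* **Outcomes.** The published outcome counts overlap: at every level they
  sum to more than the column n (a patient can, for instance, be amputated
  and later abandon treatment).  A categorical outcome needs a proper
  distribution, so the defaults take P(healed) from the printed count over
  the column n and split the residual probability across major amputation,
  abandonment and early death proportionally to their printed counts; any
  remainder is administrative censoring.
* **Time to healing.** Only the overall treatment duration (9.3 ± 9.2 weeks,
  range 1–30) and a qualitative survival figure are published.  We use
  per-level Weibull times (shape 1.6, scales 8/12/16/22 weeks for levels
  0–3) truncated to 1–30 weeks; the scales increase with severity so the
  Kaplan–Meier curves separate in the published order and the cohort-wide
  mean sits near the reported 9.3 weeks.  These scales are modelling
  choices, not published values, which is why the published log-rank and
  hazard-ratio magnitudes are checked only qualitatively.
* **Delayed mortality** (after the 52-week follow-up, within the 156-week
  horizon) is a separate per-level Bernoulli flag, excluded from the
  time-to-healing model.
* **SEWSS sums** are drawn per level from the published mean ± SD; the
  ischaemia factor is pinned to the latent level and the other nine factors
  share the remainder uniformly over their capacity (a multivariate
  hypergeometric split, each factor capped at 3).

What passing tests on this cohort do **not** show: robustness to correlated
test errors, to informative censoring, to competing risks, or to any
misspecification of the published tables themselves.  The generator
reproduces marginal summaries, not patients.

## The validation statistics

* **Cohen's kappa** `(Po − Pe)/(1 − Pe)` from the raw contingency table;
  per-level agreement dichotomises 0–3 ratings into "level L vs rest" 2×2
  tables.  Degenerate marginals (Pe = 1) are an error, not a 0/0.
* **Rate tables** report 100 · cell / column-total, rounded half-up to one
  decimal (the published tables appear to mix rounding and truncation —
  e.g. 70.37 printed as 70.3 — so comparisons allow 0.2 percentage points).
  A zero column total reports missing, not 0%.
* **Odds ratios** ad/bc with Woolf's log-method CI; the Haldane–Anscombe
  +0.5 correction fires only when a cell is zero.  The severity ladder puts
  the non-ischaemic level in the reference column.
* **Trend test** for a binary outcome over ordered levels: the
  Mantel–Haenszel statistic (n − 1)r² with equally spaced scores 0–3
  (scores are not published; the statistic is invariant to affine score
  changes anyway), df = 1.
* **Kruskal–Wallis** for continuous baselines wraps the standard
  tie-corrected implementation in `stats`; a fully tied sample is defined
  as H = 0.
* **Kaplan–Meier / log-rank / Cox** treat healing as the event; amputation,
  abandonment, death and follow-up end are right-censored.  This ignores
  competing risks deliberately — the published analysis does the same, and
  a Fine–Gray model is out of scope.  The log-rank test uses the
  hypergeometric variance over k − 1 groups (pseudo-inverse fallback for a
  group absent from all risk sets).  The Cox fit maximises the Breslow
  partial likelihood by Newton–Raphson with step-halving, convergence when
  the update norm drops below 1e-9 (50 iterations maximum, non-convergence
  is an error, |β| > 15 flags monotone likelihood).  Breslow ties suffice
  at weekly resolution; the reference level is severe (level 3), so hazard
  ratios read "how much faster does a milder level heal".

Every statistic is cross-checked in the test suite against an independent
route — `survival`, `e1071`, `stats::kruskal.test`, a saturated logistic
fit, brute-force expansion of the trend correlation, and a grid maximiser
of the partial likelihood — on hundreds of randomised small instances.

## Problem sizes and reproducibility

All randomness flows from a single integer seed; a rerun with the same
configuration is byte-identical, which the test suite asserts on the full
report bundle.  The default study-scale cohort is n = 235 (159/24/25/27);
distributional recovery is tested at n = 10,000 (multinomial), at which the
scored level shares sit within two percentage points of the published
67.6/10.2/10.6/11.5% composition and the per-level outcome frequencies lie
within three standard errors of their generating probabilities.  Oracle
equivalence suites use 500 randomised instances per statistic.

## Known limitations

* Several published percentages and odds ratios are not derivable from the
  published counts (a moderate-level pulse rate of 8.5% for 2/25, healing
  percentages 88.7/57.7/40.7/12.9 against counts giving 84.3/62.5/44.0/14.8,
  and the OR set 74.4/51.9/4.6/3.4).  The package reproduces the
  counts-based values and treats the printed ones as unverifiable.
* The published per-level kappas (0.91/0.70/0.68/0.94), hazard ratios
  (9.5, 13.8) and log-rank 44.2 require the unpublished individual-level
  data; the package exposes the machinery and checks the qualitative
  pattern (agreement highest at the scale ends, healing hazard ordered by
  severity, a strongly significant log-rank) on synthetic cohorts.
* Waveform analysis is taken as a category; no signal processing.
* Single-covariate Cox only; no multivariable adjustment, no competing
  risks.
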
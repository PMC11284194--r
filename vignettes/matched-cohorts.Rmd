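---
title: "Matched-cohort construction for aneurysm surgery comparisons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Matched-cohort construction for aneurysm surgery comparisons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aneumatch)
```

## The matching model

`aneumatch` pairs each case of a small treatment arm (the "aneurysm of
interest", AOI) with its most similar counterpart from a larger reference
arm, so that a two-group outcome comparison inherits as little confounding
as a retrospective design allows. Similarity is case-based reasoning by
k-nearest-neighbour retrieval: features are Z-score standardized,

$$z_l = \frac{x_l - \bar{x}_l}{s_l},$$

and two cases $x$ and $q$ are compared by the weighted Euclidean
dissimilarity

$$\mathrm{dist}(x, q) = \sqrt{\sum_{l=1}^{N} fw_l \,(x_l - q_l)^2},$$

with every feature weight $fw_l = 1$ by default and $k = 3$ neighbours, a
deliberately small $k$ for cohorts of a few dozen cases. Unruptured
aneurysms are matched on gender, age at surgery, aneurysm shape and
aneurysm size ($N = 4$); ruptured aneurysms additionally use the Hunt &
Hess score and the Fisher grade ($N = 6$), because rupture severity
dominates prognosis after subarachnoid hemorrhage.

Matching is constrained to strata defined by rupture status and by the
frontal base-dome-angle (FDA) quadrant. The FDA is the angle between the
aneurysm's maximum-height axis and a baseline parallel to the frontal skull
base on sagittal imaging, binned into four 90° categories; it encodes the
dome's orientation relative to the surgical corridor, which is exactly the
anatomical property that makes one approach preferable to the other, so
pairs must share it.

### Three neighbour-weighting variants

All variants rank candidates by the same distance and therefore return the
same neighbour *set*; they differ in the influence weight attached to each
neighbour:

1. **plain** — each of the $k$ neighbours has equal impact, weight $1/k$;
2. **inverse_distance** — weights proportional to $1/d$, normalized to
   sum 1;
3. **minmax_inverse** — all pool distances are first rescaled to $[0, 1]$
   by $(d - d_{\min})/(d_{\max} - d_{\min})$, then inverse-weighted as in
   variant 2.

Two degeneracies need a policy the formulas do not supply. If any distance
is exactly 0, inverse weighting is undefined; the zero-distance neighbours
share weight 1 equally and the rest get 0. If $d_{\max} = d_{\min}$, min–max
rescaling is undefined and weights fall back to equal. A structural
consequence worth knowing: under variant 3 the nearest neighbour's rescaled
distance is *always* 0 (it is the pool minimum), so the zero-distance rule
concentrates all weight on the top neighbour. We implement the formulas as
stated and document the collapse rather than inventing a smoothing term.
Because pair selection uses only the ranking, the choice of variant never
changes the matched cohort; the weights are reported for exploration.

### Sequential assignment and conflict adjudication

AOIs are processed in ascending case-id order ("next in line"), each
proposing its top-ranked stratum-mate. References are used at most once.
When two AOIs claim the same reference, the contested case goes to the
claimant at smaller raw distance (ties to the lower case id) and the loser
falls back to its second, then third, neighbour not yet assigned. This
deterministic rule replaces the expert review a clinical team would apply
to the lower-ranked matches; the `adjudicator` argument of
`sequential_match()` accepts a custom policy so recorded expert decisions
can be replayed. The greedy smaller-distance rule need not minimize the
*total* matched distance over all feasible assignments — deliberately so:
it mirrors a sequential clinical workflow, not an optimal-transport solver,
and every adjudication is logged so the audit trail is complete.

Two feasibility safeguards extend the basic procedure:

* **Stratum merging.** A category whose references cannot support its AOIs
  — none at all, or fewer than needed for one-to-one matching — is merged
  with a neighbouring category (next category up first, then down, then two
  away), cell by cell, and each affected AOI is logged. Merging whole cells
  keeps a single standardization pool per stratum and mirrors how a
  borderline case would simply be "included in the neighbouring cohort for
  matching purposes".
* **Neighbour extension.** `resolve_conflicts()` itself errors when a
  claimant exhausts its $k$ neighbours. Inside the full matcher, that error
  is caught, the loser's ranking is widened to the whole stratum pool, and
  a `neighbour_extension` event is logged — one-to-one completeness of the
  matched cohort takes precedence over the retrieval depth $k$ at the
  workflow level.

### Numerical choices

* Standardization uses the $n - 1$ denominator and is computed over the
  *stratum pool* (the stratum's AOIs plus its candidates), not globally.
  Distances are only ever compared within a pool, and per-pool scaling
  keeps each feature's contribution comparable across strata of different
  composition. This is a package choice and is flagged here because either
  convention is defensible.
* Constant columns in a pool (common in small strata — e.g. an all-female
  stratum) cannot be scaled; they are mapped to zero with a warning and
  simply carry no matching information.
* Binary features enter the Euclidean distance 0/1-encoded before
  standardization (gender: male = 0, female = 1; shape: regular = 0,
  irregular = 1); ordinal grades enter as their integer level. This keeps
  the single distance formula applicable to every matched feature.
* FDA boundary policy: categories are the intervals $[0, 90]$, $(90, 180]$,
  $(180, 270]$, $(270, 360]$. Printed category ranges with ".1" lower
  bounds imply one-decimal measurement granularity; treating the bins as
  upper-closed makes the classifier total on the continuum. 360° is
  accepted as the top of category 4 and not wrapped to 0.

## The comparison engine

Per variable, the test is routed by explicit rules and the full routing
trace (minimum expected cell count, per-group normality p, Levene p) is
returned alongside the result:

* binary/categorical → Pearson chi-square without continuity correction,
  unless any expected cell count (row × column / N) is below 5, in which
  case Fisher's exact test substitutes (two-sided by the point-probability
  method);
* ordinal/metric → per-group normality screening at $\alpha = 0.05$ using
  the Lilliefors correction (the plain Kolmogorov–Smirnov test with
  estimated mean and SD is anti-conservative); either group failing routes
  to the Mann–Whitney U test, both passing routes to the t-test, pooled if
  Levene's mean-centred test gives $p \ge 0.05$ and Welch otherwise.

The Mann–Whitney U statistic comes from midrank sums; the p-value is exact
when the combined sample size is at most 20 with no ties, and otherwise
uses the normal approximation with tie and continuity corrections. Groups
too small ($n < 4$) or constant cannot be screened for normality and are
routed as non-normal. A variable whose pooled sample is constant (e.g. a
comorbidity absent from both arms) offers no contrast; its test is skipped
and rendered as an em-dash. All tests are two-sided; no multiple-testing
correction is applied by default (a Holm option exists) because the output
mirrors the per-variable presentation conventional in clinical baseline
tables.

Primary outcomes are the degree of aneurysm occlusion (binary) and the
modified Rankin Scale at discharge (ordinal, 0–6); secondary outcomes are
temporary clipping, intraoperative rupture, postoperative stroke and
hemorrhage, hydrocephalus, ventriculoperitoneal-shunt dependency and
vasospasm, all binary.

## What the synthetic generator does and does not emulate

`generate_cohort()` draws a two-arm cohort from one seeded stream. The
defaults encode the structure of the motivating study design: 14 AOI-arm
vs 36 reference-arm candidates, a 50% rupture rate, a 12:2 female:male
ratio, and Table-style comorbidity prevalences (hypertension 11/28,
nicotine abuse 10/28, multiple aneurysms 9/28, heart disease 5/28,
ischemic stroke 3/28, obesity 2/28, peripheral arterial disease 1/28;
diabetes, thrombosis and alcohol abuse structurally absent). Where only
summary statistics are plausible anchors, distributional shapes are
implementer choices: age is normal(55, 10) truncated to [18, 95] years;
aneurysm size is log-normal with median 7 mm (sdlog 0.5), a standard shape
for size measurements; Hunt & Hess and Fisher grades are categorical with
mass centred at grades 1–2 and 2–3 respectively; the mRS mass is
front-loaded with a smaller poor-outcome mode; dome angles are uniform on
[0°, 360°). Binary outcome rates default to *equal* arms, so the generator's
default regime is the sharp null used for calibrating the comparison
engine; planted effects are explicit arguments.

The generator does not model inter-rater measurement error, imaging
statistics, correlated comorbidities, or informative loss to follow-up.
Passing recovery and calibration tests therefore demonstrates that the
machinery is correct under a known data-generating process — not that any
particular clinical dataset satisfies these distributional assumptions.

`plant_twins()` supplies ground truth for recovery experiments: one jittered
copy per AOI (continuous features perturbed by `noise_scale` × the AOI-pool
SD, binaries flipped with `flip_prob`, grades shifted one level with
`flip_prob`), keeping rupture status and FDA category, plus decoys drawn
from the generator's marginals but constrained to the same stratum so they
genuinely compete. Two decoys per AOI reproduce the ~36:14 pool ratio.

## Calibration behaviour and known limitations

`calibrate_type1()` measures each routed test's empirical type-I error on
replicated null cohorts. At 14 cases per arm, the discrete tests are
conservative by construction: the expected-cell-count gate sends only
well-populated 2×2 tables to the chi-square test, whose conditional
rejection rate at nominal $\alpha = 0.05$ then sits near 0.037 — an exact
enumeration over all pairs of binomial counts reproduces this value, so the
shortfall is a property of discreteness at this sample size, not an
implementation artifact. Fisher's exact test is more conservative still
(rate ≈ 0.02), as exact conditional tests are; the Mann–Whitney and t
routes hold their nominal size. Users comparing arms of this size should
read non-significance accordingly.

Other limitations worth stating plainly: the matcher is greedy-sequential
by design (no optimal or propensity-score matching); distances are only
defined within strata, so the exported distance matrix has no cross-stratum
entries; conflict adjudication between claimants whose pools were merged
compares distances from a shared standardization pool, but expert replay
via a custom adjudicator is trusted blindly; and vessel/inclination angles
are carried as passthrough measurements without entering the matching.

## Problem sizes used in the shipped checks

The test suite and `scripts/acceptance.R` exercise: planted-twin recovery
over 20 zero-noise and 100 noise-0.05 replicates of 14-AOI cohorts with two
decoys per AOI; k-NN-versus-brute-force agreement on pools up to 200 cases;
metric-axiom checks on 10,000 random triples; type-I calibration on 2000
null cohorts of 14 + 14 cases; Fisher-exact agreement with full enumeration
for all 2×2 tables with $N \le 14$ plus random tables up to $N = 40$; and
exact Mann–Whitney agreement with labeling enumeration for combined
$n \le 12$. These sizes give stable Monte-Carlo estimates (binomial 99%
bands at 2000 replicates span roughly ±0.013 around 0.05) while keeping a
full run in the order of a minute or two.
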
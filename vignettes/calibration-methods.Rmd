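---
title: "Calibrating in-frame indel predictors into ACMG/AMP evidence strengths"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating in-frame indel predictors into ACMG/AMP evidence strengths}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(indelcal)
```

## The problem

Computational variant-effect predictors emit continuous scores, but
clinical variant classification under the ACMG/AMP guidelines consumes
discrete evidence strengths (supporting, moderate, strong, for either
pathogenicity or benignity). Using a tool's default decision threshold as
clinical evidence typically overweights it. `indelcal` implements the
calibration chain that turns labeled score samples for in-frame insertions
and deletions into per-level score intervals:

1. **dataset construction** — clinical, population and genotype-quality
   filters with per-rule audit counts, exact-key overlap exclusion, indel
   typing by net length change;
2. **prior estimation** — the prior probability that a rare in-frame indel
   in a disease-associated gene is pathogenic, estimated from a labeled
   positive sample and an unlabeled population sample in feature space
   (positive-unlabeled estimation via a nearest-neighbour distance curve);
3. **the point-based evidence framework** — a per-point likelihood ratio
   `s` anchored to the ACMG/AMP posterior floors, giving the minimum LR
   `s^k` for each evidence level `k`;
4. **local posterior calibration** — adaptive-window estimates of
   `P(pathogenic | score ≈ x)` reweighted to the prior, with one-sided 95%
   bootstrap bounds, from which per-level thresholds are read off on the
   stringent side;
5. **evaluation** — evidence assignment, bin occupancy, bin likelihood
   ratios against the framework's expected minima, length-stratified
   checks and per-proband evidence yield.

Insertions and deletions are always calibrated independently, with their
own priors: insertions carry a markedly lower prior of pathogenicity, so
the same posterior floors translate into stricter score thresholds.

## The evidence framework

Evidence strength is counted in signed points. With prior `α`, the
Bayesian combination rule requires the posterior after six points of
pathogenic evidence to sit exactly at the likely-pathogenic floor of 0.90.
The per-point likelihood ratio therefore solves
`posterior(s^6, α) = 0.90`, i.e.

```
s(α) = (9 (1 − α) / α)^(1/6)
```

and level `k` demands an LR of at least `s^k` (for benign levels the bound
is `s^-k`, i.e. an inverse LR of at least `s^k`).

```{r}
round(as.numeric(per_point_lr(0.046)), 2)   # deletion prior
point_scale(0.046)
```

`validate_point_scale()` checks the ACMG/AMP anchors (0.99 at ten points,
0.90 at six, ≤ 0.10 at minus six). For priors at or above 0.9 the scale is
degenerate (`s ≤ 1`) and is flagged rather than refused.

## Local posterior estimation

Scores are first *oriented* so that higher always means more pathogenic
(`orient_scores()`); all thresholds are reported back in the tool's native
units. At each of `grid_size` evenly spaced points spanning the pooled
score range, a symmetric window expands until it holds at least
`min_count` pooled calibration scores **and** at least `min_class` scores
of each class; the posterior is then

```
post(x) = α c_P/n_P / (α c_P/n_P + (1 − α) c_B/n_B)
```

so the labeled class frequencies are reweighted to the prior.

**Window sizing.** The windowing rule behind published local-posterior
calibrations is not fully specified, so the rule here is the package's own
choice, made on bias–variance grounds and configurable via
`window_rule()`:

* `min_count` defaults to `max(100, ceiling(0.06 n))` for `n` pooled
  scores. A fixed small count makes the estimator's variance at any fixed
  score grow arbitrarily large relative to the posterior scale as the
  minority class thins out; a window that is a fixed small fraction of the
  sample keeps the pointwise standard error roughly stable as datasets
  grow, at the cost of a smoothing bias that is negligible at the sample
  sizes involved (verified against the analytic posterior on synthetic
  Gaussian data, below).
* `min_class = 10` guarantees that no window estimates a class density
  from fewer than 10 points. Without it, windows in score regions
  dominated by one class produce posterior estimates that jump between 0/1
  and interior values depending on whether a handful of minority-class
  points fall inside.

Windows are closed on both ends; counting uses binary search over the
sorted score vectors (compiled), so a full 10,000-replicate bootstrap on
5,000 + 5,000 scores and a 1,001-point grid runs in well under a minute on
one CPU.

**Where the estimator is identified.** A local posterior is only
estimable where *both* class-conditional densities have data. In the far
upper tail of a well-separated tool the benign density is essentially
zero: no estimator, at any smoothing, attains uniform pointwise accuracy
there from a few thousand scores. The package's oracle-equivalence test
therefore compares the estimate with the analytic posterior over the
intersection of the per-class 5th–95th percentile ranges; outside that
region the procedure protects itself differently — through the stringent
bootstrap bound and the extreme-support exclusion below.

## Bootstrap bounds and threshold extraction

`bootstrap_bounds()` resamples the pathogenic and benign lists
independently with replacement at their original sizes (default
`B = 10000`), recomputes the full curve including window re-selection, and
keeps the pointwise 5th and 95th percentiles. Thresholds are read off the
*stringent* side: the lower bound for pathogenic levels and the upper
bound for benign levels, a one-sided 95% bound each way.

For level `+k`, the threshold is the least oriented score `t` such that
the lower bound stays at or above `posterior_threshold_for_level(α, k)`
for *every* grid point at or beyond `t` (a suffix condition, so a dip
anywhere above `t` pushes the threshold outward). Benign levels mirror
this below. A level is reported only if at least `min_support` calibration
scores (default 10, both classes pooled) lie at or beyond its threshold;
otherwise it is excluded with the reason `"insufficient extreme support"`.
Published threshold tables do not state the support rule behind their
excluded entries; 10 pooled variants is a deliberately conservative,
configurable default.

Intervals between consecutive attained thresholds are emitted with each
boundary belonging to the **stronger** level, reproducing the published
interval conventions (e.g. a `+1` interval `[0.961, 0.982)` with
`≥ 0.982` as `+2`). For tools where lower scores mean more pathogenic, the
oriented intervals are mirrored back, which flips the bracket types.

```{r}
tr <- synthetic_truth(
  score_dist_spec("gaussian", list(mean = 2, sd = 1)),
  score_dist_spec("gaussian", list(mean = 0, sd = 1)),
  prior = 0.046, seed = 1)
ss <- gen_two_class_scores(tr, 2000, 2000, seed = 1)
cv <- bootstrap_bounds(ss, 0.046, B = 500, seed = 1)
extract_thresholds(cv, point_scale(0.046), min_support = 10)
```

## Prior estimation from positive-unlabeled data

The prior is estimated without benign labels: the unlabeled population
sample is treated as a mixture of a fraction `α` of pathogenic-like
variants and `1 − α` benign-like ones, in a feature space where the two
components differ. `build_distance_curve()` repeatedly draws a labeled
positive at random, records the Euclidean distance to its nearest
remaining unlabeled point, removes that point, and continues until the
unlabeled copy is exhausted (ties broken by lowest row index; features are
first standardized by pooled mean and standard deviation, and the whole
traversal is averaged over `n_reps` repetitions). While positive-like
unlabeled points remain, recorded distances stay small; once they are
exhausted the curve rises. The consumed fraction at the rise estimates
`α`.

The published distance-curve method maps curves to priors with a trained
regressor; this package instead uses a deterministic knee rule so that no
trained weights are required: the mean curve is smoothed with a centred
moving average (window 5% of curve length, minimum 3), first differences
are taken, and the knee is the first position where the difference reaches
half its maximum, **plus the smoother half-width**. The half-width
correction deconvolves the known lead a centred moving average introduces
— with it, an ideal step at fraction `f` returns exactly `f`. A flat or
non-rising curve (unlabeled indistinguishable from positives) returns
`α̂ = 1` with a degeneracy flag. Recovery is tested over planted fractions
α ∈ {0.05, 0.2, 0.4}; estimation error grows as the component separation
shrinks, which the suite checks explicitly at separations {3, 1, 0.25}.

`estimate_priors_stratified()` runs the procedure on the full samples and
on the insertion-only and deletion-only subsets, mirroring the stratified
deletion-versus-insertion priors the calibration consumes.

## What the synthetic data emulates — and what it does not

The generators in this package produce every input the pipeline consumes,
with planted ground truth:

* `gen_two_class_scores()` — class-conditional score distributions
  (Gaussian for unbounded log-likelihood-ratio-style tools, Beta on
  \[0, 1\] for probability-like tools, or mixtures), retaining the truth
  object so the analytic posterior is available as an oracle;
* `gen_pu_features()` — positive/unlabeled Gaussian feature matrices with
  a planted mixing fraction (exact-count by default, so recovery tests are
  sharp);
* `gen_filter_fixture()` — variant tables exercising every clinical filter
  rule, with the expected per-rule audit planted;
* `gen_proband_cohort()` — per-proband score tables with planted per-level
  counts, every score guaranteed inside its level's interval.

These emulate the *statistical shape* the calibration consumes — two-class
score distributions, a mixture with a knowable mixing fraction, records
with the fields the filters read. They do **not** emulate real genomes:
there is no linkage, no gene structure, no realistic score multimodality,
no annotation failure modes, and the feature clusters behind prior
estimation are cleanly Gaussian. Passing tests therefore demonstrate that
the statistical machinery is correct, not that any particular published
number is reproduced: the real-data outputs (the 4.0%/0.8%/4.6% priors,
per-tool threshold tables, population bin percentages, test-set likelihood
ratios, cohort summaries) require external databases and external
predictor scores. The published per-tool threshold tables ship with the
package (`published_thresholds()`) purely as machine-readable fixtures for
interval-convention tests.

## Numerical choices and degenerate inputs

* Window intervals are closed on both ends; a relative `1e-9` guard
  absorbs floating-point rounding at window edges.
* Nearest-neighbour ties in the distance curve break to the lowest row
  index; all randomness flows from one explicit seed per call, and no
  function disturbs the caller's RNG state.
* Missing allele frequency means "absent from the population database" and
  passes the frequency filter; missing genotype fields fail their rule and
  are counted in the audit, never raised as errors.
* A zero net length change is typed `balanced` and takes no part in
  insertion/deletion calibration; variant keys are compared exactly as
  given, with no left-alignment (inputs are expected pre-normalized).
* The sequence-window cropper uses `floor` for the variant midpoint and a
  left-biased split of the even window (1023 left, 1022 right of the
  centre), shifted minimally at the termini; the convention used by
  published pipelines is unstated, so this one is fixed and documented.
* Degenerate cases return flagged values instead of failing: a flat
  distance curve (`α̂ = 1`, degeneracy flag), a prior ≥ 0.9 (degenerate
  point scale), an all-identical score sample (single-point curve with a
  warning), a curve never reaching a level (that level simply absent).
* Undefined (0/0) evaluation bins are distinguished from infinite ones;
  published tables print only infinities, but silent division artifacts on
  sparse test sets are worth surfacing.

## Problem sizes used by the test suite

The suite exercises the calibration chain at 5,000 + 5,000 scores with
1,000 bootstrap replicates for the oracle-equivalence check (the
full-scale default remains `B = 10000`), 2,000–2,500 scores with 200–400
replicates for the conservatism and prior-monotonicity properties, and
2,000 + 2,000 points with 10 distance-curve repetitions per seed for prior
recovery. These sizes keep the whole suite under a few minutes while
leaving every statistical margin wide (the recovery error at separation 3
is under 0.005 against a tolerance of 0.05).

## Known limitations

* The knee rule is a deterministic stand-in for the published
  curve-to-prior regressor; it is accurate when the unlabeled mixture's
  components are separated in feature space and degrades as they merge —
  exactly the regime the degradation test measures. It makes no attempt to
  correct for overlapping components.
* Thresholds inherit the grid resolution (defaults: 1,001 points over the
  observed range).
* The package calibrates one tool at a time; combining evidence across
  tools, and gene- or domain-specific recalibration, are out of scope.
* Bin likelihood ratios on small test sets are unstable; the
  infinite/undefined distinction surfaces this but does not repair it.
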
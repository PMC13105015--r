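# indelcal

Calibration of in-frame indel variant-effect predictors into ACMG/AMP
evidence strengths.

## What problem this solves

Short in-frame insertions and deletions (net length change a nonzero
multiple of 3, ≤ 50 bp) are common, clinically important, and hard to
interpret. Predictors score them on continuous scales, but clinical
classification under the ACMG/AMP guidelines needs discrete evidence
strengths — supporting (±1), moderate (±2), strong (±4) points — whose
combined posterior probability must clear fixed floors (≥ 0.99 pathogenic,
≥ 0.90 likely pathogenic, ≤ 0.10 likely benign, ≤ 0.01 benign). `indelcal`
is for method developers and clinical bioinformaticians who need to turn a
labeled score sample into defensible per-level score intervals, or to
audit such intervals.

The core machinery, in the field's standard notation:

* **Point-based evidence framework.** For prior probability of
  pathogenicity α, the per-point likelihood ratio
  `s(α) = (9(1−α)/α)^(1/6)` anchors six evidence points at the
  likely-pathogenic posterior floor: `posterior(s⁶, α) = 0.90`. Evidence
  level k then requires LR ≥ `s^k` (benign levels: inverse LR ≥ `s^k`).
  At the deletion prior α = 0.046, s = 2.39.
* **Local posterior calibration.** On a grid over the oriented score
  range, `P(pathogenic | score ≈ x)` is estimated from class counts in an
  adaptive window, reweighted to the prior:
  `post(x) = α·c_P/n_P / (α·c_P/n_P + (1−α)·c_B/n_B)`. A one-sided 95%
  bootstrap bound (10,000 replicates by default) gives the stringent
  curve; level-k thresholds are the scores beyond which the stringent
  bound stays above (below) the level-k posterior bound, with
  sparse-extreme levels excluded. Insertions and deletions are calibrated
  independently.
* **Positive-unlabeled prior estimation.** α is estimated from a labeled
  pathogenic sample and an unlabeled population sample in feature space by
  a nearest-neighbour distance curve whose knee marks the positive
  fraction.
* **Evaluation.** Evidence assignment with boundary-to-stronger-level
  interval conventions, per-bin likelihood ratios versus the expected
  minima `s^k`, length stratification (single vs multi amino acid), and
  per-proband evidence yield summaries.

Dataset-construction utilities (clinical/population/genotype filters with
per-rule audits, exact-key overlap exclusion, indel typing by net length
change, sequence-window cropping for protein language models) and a
synthetic-data module with planted ground truth round out the pipeline.

## Worked example

Calibrate a synthetic "tool" whose pathogenic scores are N(2,1) and benign
scores N(0,1), at the deletion prior of 4.6%:

```r
library(indelcal)

tr <- synthetic_truth(
  score_dist_spec("gaussian", list(mean = 2, sd = 1)),
  score_dist_spec("gaussian", list(mean = 0, sd = 1)),
  prior = 0.046, seed = 1)
ss <- gen_two_class_scores(tr, 2000, 2000, seed = 1, tool = "demo")

point_scale(0.046)
#> <point_scale> prior = 0.046, per-point LR s = 2.3906
#>  level expected_lr posterior_bound
#>     -4        0.03          0.0015
#>     -3        0.07          0.0035
#>     -2        0.17          0.0084
#>     -1        0.42          0.0198
#>     +1        2.39          0.1034
#>     +2        5.71          0.2160
#>     +3       13.66          0.3971
#>     +4       32.66          0.6116

curve <- bootstrap_bounds(ss, prior = 0.046, B = 1000, seed = 1)
thr <- extract_thresholds(curve, point_scale(0.046), min_support = 10)
thr
#> <evidence_thresholds> demo / deletion (higher_pathogenic), prior = 0.046
#>  level                interval support_n excluded_reason
#>     -4        (-Inf, -2.23996]        35            <NA>
#>     -3   (-2.23996, -0.706578]       478            <NA>
#>     -2 (-0.706578, -0.0988365]       972            <NA>
#>     -1  (-0.0988365, 0.406056]      1418            <NA>
#>      1      [1.60284, 2.17318)      1430            <NA>
#>      2      [2.17318, 2.60327)       874            <NA>
#>      3      [2.60327, 3.01467)       574            <NA>
#>      4          [3.01467, Inf)       316            <NA>

assign_points(c(1.8, 0.2, -1.5), thr)$level
#> [1]  1 -1 -3
```

Reading the output: the per-point table says a score region can count as
supporting pathogenic evidence (+1) only if its local posterior stays
above 0.1034; the extracted intervals say a score of 1.8 earns +1, a score
of 0.2 falls in the supporting-benign interval (−1), and −1.5 reaches −3.
Each interval's `support_n` is the number of calibration scores at or
beyond its threshold; levels with fewer than `min_support` would be listed
with `excluded_reason = "insufficient extreme support"`. The intervals'
boundary scores always belong to the stronger level, matching the
conventions of published threshold tables, machine-readable copies of
which ship in `inst/extdata/` (see `published_thresholds()`).

An end-to-end run (simulate → calibrate → evaluate) with a deterministic
manifest:

```r
run_pipeline(list(stages = c("simulate", "calibrate", "evaluate"),
                  out_dir = "run1", seed = 9,
                  priors = list(deletion = 0.046, insertion = 0.008),
                  direction = "higher_pathogenic", bootstrap_B = 1000))
```

A thin command-line wrapper with the same stages lives at
`inst/cli/indelcal.R`.

See `vignettes/calibration-methods.Rmd` for the model, the window rule,
the knee rule behind prior estimation, and all numerical conventions.

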
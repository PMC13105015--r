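Package: indelcal
Title: Calibration of In-Frame Indel Effect Predictors into ACMG/AMP Evidence Strengths
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Converts continuous variant-effect-predictor scores for in-frame
    insertions and deletions into ACMG/AMP evidence-strength intervals.
    Provides clinical/population/genotype variant filtering with per-rule
    audits, class-prior estimation from positive-unlabeled feature data via a
    nearest-neighbour distance curve, the point-based Bayesian likelihood-ratio
    evidence framework, local posterior probability calibration with one-sided
    bootstrap confidence bounds, threshold extraction with extreme-support
    exclusion, and downstream evaluation (evidence assignment, bin likelihood
    ratios, length stratification, per-proband evidence yield). A synthetic
    data module generates every input with known ground truth so the whole
    pipeline is testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
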
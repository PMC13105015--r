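# Shared builders for the test suite. Everything is generated in code; the
# only stored fixtures are the published threshold tables under extdata.

gaussian_truth <- function(prior = 0.046, mu_path = 2, mu_benign = 0, sd = 1,
                           seed = 1) {
  synthetic_truth(
    score_dist_spec("gaussian", list(mean = mu_path, sd = sd)),
    score_dist_spec("gaussian", list(mean = mu_benign, sd = sd)),
    prior = prior, seed = seed)
}

# hand-built thresholds object (higher_pathogenic) from a compact spec:
# intervals follows the package's own convention, boundary to stronger level
toy_thresholds <- function(levels_df, tool = "toy", variant_type = "deletion",
                           direction = "higher_pathogenic", prior = 0.046) {
  n <- nrow(levels_df)
  if (is.null(levels_df$threshold)) levels_df$threshold <- rep(NA_real_, n)
  if (is.null(levels_df$support_n)) levels_df$support_n <- rep(NA_integer_, n)
  if (is.null(levels_df$excluded_reason))
    levels_df$excluded_reason <- rep(NA_character_, n)
  indelcal:::new_evidence_thresholds(tool, variant_type, direction, prior,
                                     levels_df)
}

published_by_tool <- function(variant_type) {
  thr <- published_thresholds(variant_type)
  names(thr) <- vapply(thr, function(x) x$tool, character(1))
  thr
}
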
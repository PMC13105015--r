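# Application of calibrated thresholds to new data: per-variant evidence
# assignment, bin occupancy, bin-level likelihood ratios against the
# framework's expected minima, length stratification and per-proband
# evidence yield.

in_interval <- function(score, lo, hi, lo_inc, hi_inc) {
  lo_ok <- if (is.finite(lo)) { if (lo_inc) score >= lo else score > lo } else TRUE
  hi_ok <- if (is.finite(hi)) { if (hi_inc) score <= hi else score < hi } else TRUE
  lo_ok & hi_ok
}

#' Assign evidence points to scores
#'
#' Maps each score to the unique evidence level whose interval contains it
#' (intervals are in the tool's original units; boundaries already belong to
#' the stronger level by construction). Scores falling between the attained
#' benign and pathogenic intervals are level 0 (indeterminate); missing
#' scores yield a missing level.
#'
#' @param score Numeric vector of scores in the tool's original units.
#' @param thresholds An `evidence_thresholds` object.
#' @return A data frame with columns `score`, `level`, `tool`,
#'   `variant_type`.
#' @export
assign_points <- function(score, thresholds) {
  stopifnot(inherits(thresholds, "evidence_thresholds"))
  tab <- thresholds$levels[is.na(thresholds$levels$excluded_reason), , drop = FALSE]
  level <- ifelse(is.na(score), NA_integer_, 0L)
  if (nrow(tab)) {
    for (i in seq_len(nrow(tab))) {
      hit <- !is.na(score) &
        in_interval(score, tab$interval_low[i], tab$interval_high[i],
                    tab$low_inclusive[i], tab$high_inclusive[i])
      level[hit] <- tab$level[i]
    }
  }
  data.frame(score = score, level = level, tool = thresholds$tool,
             variant_type = thresholds$variant_type,
             stringsAsFactors = FALSE)
}

#' Percentage of scores falling into each evidence bin
#'
#' @param scores Numeric vector (may contain `NA` = unscored variants).
#' @param thresholds An `evidence_thresholds` object.
#' @return A list with `percent` (named vector over levels including 0,
#'   summing to 100 over scored variants), `n_scored` and
#'   `unscored_fraction`.
#' @export
bin_percentages <- function(scores, thresholds) {
  if (length(scores) < 1L) abort_input("empty score list")
  lev <- assign_points(scores, thresholds)$level
  scored <- lev[!is.na(lev)]
  if (!length(scored)) abort_input("no scored variants")
  all_levels <- sort(unique(c(0L,
    thresholds$levels$level[is.na(thresholds$levels$excluded_reason)])))
  counts <- vapply(all_levels, function(k) sum(scored == k), integer(1))
  pct <- 100 * counts / length(scored)
  names(pct) <- sprintf("%+d", all_levels)
  names(pct)[all_levels == 0L] <- "0"
  list(percent = pct, n_scored = length(scored),
       unscored_fraction = mean(is.na(lev)))
}

#' Bin-level likelihood ratios on a labeled test set
#'
#' For each attained evidence level, computes the likelihood ratio of the
#' bin: the fraction of all pathogenic test variants landing in the bin over
#' the fraction of all benign test variants landing there. Benign levels are
#' reported as the inverse ratio (so larger is better on both sides). A bin
#' with members of one class only is infinite; an empty bin is undefined
#' (`NaN`), distinct from infinite.
#'
#' @param scores Numeric score vector.
#' @param labels Character vector, `"pathogenic"` or `"benign"`, same length.
#' @param thresholds An `evidence_thresholds` object.
#' @return A data frame with one row per attained non-zero level: `level`,
#'   `n_path_in_bin`, `n_benign_in_bin`, `n_path_total`, `n_benign_total`,
#'   `lr`, `reported_as` (`"standard"`/`"inverse"`), `defined`.
#' @export
bin_likelihood_ratios <- function(scores, labels, thresholds) {
  if (length(scores) != length(labels))
    abort_input("scores and labels must have equal length")
  if (!all(labels %in% c("pathogenic", "benign")))
    abort_input("labels must be 'pathogenic' or 'benign'")
  nP <- sum(labels == "pathogenic"); nB <- sum(labels == "benign")
  if (nP == 0L) abort_input("test set contains no pathogenic variants")
  if (nB == 0L) abort_input("test set contains no benign variants")
  lev <- assign_points(scores, thresholds)$level
  ks <- sort(setdiff(
    thresholds$levels$level[is.na(thresholds$levels$excluded_reason)], 0L))
  rows <- lapply(ks, function(k) {
    inb <- !is.na(lev) & lev == k
    cP <- sum(inb & labels == "pathogenic")
    cB <- sum(inb & labels == "benign")
    std <- (cP / nP) / (cB / nB)   # TPR/FPR; Inf when cB = 0, NaN when 0/0
    lr <- if (k > 0) std else 1 / std
    data.frame(level = k, n_path_in_bin = cP, n_benign_in_bin = cB,
               n_path_total = nP, n_benign_total = nB, lr = lr,
               reported_as = if (k > 0) "standard" else "inverse",
               defined = !(cP == 0L && cB == 0L),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$lr[!out$defined] <- NaN
  out
}

#' Compare bin likelihood ratios to the framework's expected minima
#'
#' Pathogenic level +k passes when its standard LR is at least `s^k`; benign
#' level -k passes when its inverse LR is at least `s^k` (equivalently, the
#' standard LR is at most `s^-k`). Undefined (empty) bins are not evaluable.
#'
#' @param bin_lrs Output of [bin_likelihood_ratios()].
#' @param scale A [point_scale()] matching the calibration prior.
#' @return `bin_lrs` with added columns `expected_lr` (the bound on the
#'   reported scale) and `pass` (`NA` for non-evaluable bins).
#' @export
compare_to_expected <- function(bin_lrs, scale) {
  stopifnot(inherits(scale, "point_scale"))
  s <- scale$per_point_lr
  bin_lrs$expected_lr <- s^abs(bin_lrs$level)
  bin_lrs$pass <- ifelse(!bin_lrs$defined, NA, bin_lrs$lr >= bin_lrs$expected_lr)
  bin_lrs
}

#' Partition in-frame indels by length
#'
#' Single amino-acid indels (net change of exactly 3 nucleotides) versus
#' longer in-frame indels. Frameshift input (net change not a multiple of 3)
#' is an input error.
#'
#' @param net_nt Signed net nucleotide length changes.
#' @return Character vector, `"single_aa"` or `"multi_aa"`.
#' @export
stratify_by_length <- function(net_nt) {
  if (any(is.na(net_nt)) || any(net_nt %% 3L != 0L) || any(net_nt == 0L))
    abort_input("length stratification requires in-frame, length-changing variants")
  ifelse(abs(net_nt) == 3L, "single_aa", "multi_aa")
}

#' Per-proband evidence-yield summary
#'
#' Counts evidence assignments per level for each proband and reports the
#' mean and (min-max) range across probands. Probands present in the cohort
#' but without scored variants contribute zeros at every level.
#'
#' @param cohort Data frame with columns `proband_id` and `score` (scores in
#'   the tool's original units; `NA` = unscored).
#' @param thresholds An `evidence_thresholds` object.
#' @param probands Optional character vector of all proband ids (to include
#'   probands with no variants at all); defaults to those present.
#' @return A data frame with one row per level (attained levels plus 0):
#'   `level`, `mean`, `min`, `max`.
#' @export
proband_evidence_summary <- function(cohort, thresholds, probands = NULL) {
  if (!is.data.frame(cohort) || !all(c("proband_id", "score") %in% names(cohort)))
    abort_input("cohort must have proband_id and score columns")
  probands <- probands %||% unique(cohort$proband_id)
  if (length(probands) < 1L) abort_input("empty cohort")
  lev <- assign_points(cohort$score, thresholds)$level
  all_levels <- sort(unique(c(0L,
    thresholds$levels$level[is.na(thresholds$levels$excluded_reason)])))
  pb <- factor(cohort$proband_id, levels = probands)
  rows <- lapply(all_levels, function(k) {
    per <- tapply(!is.na(lev) & lev == k, pb, sum, default = 0L)
    per[is.na(per)] <- 0L
    data.frame(level = k, mean = mean(per), min = min(per), max = max(per))
  })
  do.call(rbind, rows)
}
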
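# Local posterior probability calibration. Scores are first oriented so
# that higher always means more pathogenic; the local posterior at a score
# is estimated from class counts in an adaptive symmetric window, reweighted
# to the prior; a one-sided bootstrap bound supplies the stringent curve
# from which per-level thresholds are read off.

#' Adaptive window rule for the local posterior estimator
#'
#' The window at a grid point is the smallest symmetric interval holding at
#' least `min_count` calibration scores (both classes pooled) and at least
#' `min_class` scores of each class; each constraint saturates at the full
#' data range. The per-class floor keeps the estimator from degenerating in
#' score regions where the minority class thins out; the pooled floor
#' controls variance in the interior.
#'
#' @param min_count Minimum pooled score count per window. The default
#'   (`NULL`) scales with the data: `max(100, ceiling(0.06 * n))` for `n`
#'   pooled calibration scores, which keeps the window a roughly constant
#'   fraction of the sample as datasets grow.
#' @param grid_size Number of evenly spaced evaluation points spanning the
#'   pooled score range (default 1001).
#' @param min_class Minimum count of each class per window (default 10).
#' @return A `window_rule` object.
#' @export
window_rule <- function(min_count = NULL, grid_size = 1001L, min_class = 10L) {
  if (!is.null(min_count) && !is_count(min_count))
    abort_config("`min_count` must be a count >= 1 (or NULL for the adaptive default)")
  if (!is_count(grid_size, min = 2L)) abort_config("`grid_size` must be >= 2")
  if (!is_count(min_class, min = 0L)) abort_config("`min_class` must be a count >= 0")
  structure(list(min_count = if (is.null(min_count)) NULL else as.integer(min_count),
                 grid_size = as.integer(grid_size),
                 min_class = as.integer(min_class)),
            class = "window_rule")
}

resolve_min_count <- function(rule, n_pooled) {
  rule$min_count %||% max(100L, as.integer(ceiling(0.06 * n_pooled)))
}

#' Orient a score set so that higher means more pathogenic
#'
#' Tools with `direction = "lower_pathogenic"` have their scores negated;
#' the original direction is retained so results are reported back in the
#' tool's native units. Applying the function twice restores the original
#' values.
#'
#' @param set A [score_set()].
#' @return The oriented (or re-inverted) `score_set`.
#' @export
orient_scores <- function(set) {
  stopifnot(inherits(set, "score_set"))
  if (set$direction == "lower_pathogenic") {
    set$pathogenic_scores <- -set$pathogenic_scores
    set$benign_scores <- -set$benign_scores
    set$oriented <- !isTRUE(set$oriented)
  } else {
    set$oriented <- TRUE
  }
  set
}

ensure_oriented <- function(set) if (isTRUE(set$oriented)) set else orient_scores(set)

posterior_from_counts <- function(c_path, c_benign, n_path, n_benign, prior) {
  num <- prior * c_path / n_path
  den <- num + (1 - prior) * c_benign / n_benign
  out <- num / den
  out[den == 0] <- NaN
  out
}

#' Local posterior probability at a single score
#'
#' Expands a symmetric window around `point` until it holds at least
#' `rule$min_count` pooled calibration scores, then returns the
#' prior-reweighted posterior
#' \eqn{(\alpha c_P/n_P) / (\alpha c_P/n_P + (1-\alpha) c_B/n_B)}.
#'
#' @param point A score on the oriented axis (higher = more pathogenic).
#' @param set A [score_set()]; oriented internally if needed.
#' @param prior Prior probability of pathogenicity in (0, 1).
#' @param rule A [window_rule()].
#' @return A list with `posterior`, `half_width`, `c_path`, `c_benign`.
#' @export
local_posterior_at <- function(point, set, prior, rule = window_rule()) {
  set <- ensure_oriented(set)
  if (!is_fraction(prior, open = TRUE))
    abort_input("`prior` must lie strictly inside (0, 1)")
  sp <- sort(set$pathogenic_scores); sb <- sort(set$benign_scores)
  mc <- resolve_min_count(rule, length(sp) + length(sb))
  w <- local_window_counts(sp, sb, as.numeric(point), mc, rule$min_class)
  post <- posterior_from_counts(w$c_path, w$c_benign,
                                length(sp), length(sb), prior)
  list(posterior = post, half_width = w$half_width,
       c_path = w$c_path, c_benign = w$c_benign)
}

new_posterior_curve <- function(grid, estimate, half_width, c_path, c_benign,
                                set, prior, rule, lower = NULL, upper = NULL,
                                B = NULL, seed = NULL) {
  structure(list(grid = grid, estimate = estimate,
                 lower = lower, upper = upper,
                 half_width = half_width, c_path = c_path, c_benign = c_benign,
                 tool = set$tool, variant_type = set$variant_type,
                 direction = set$direction,
                 oriented_scores = sort(c(set$pathogenic_scores,
                                          set$benign_scores)),
                 n_path = length(set$pathogenic_scores),
                 n_benign = length(set$benign_scores),
                 prior = prior,
                 settings = list(min_count = resolve_min_count(
                                   rule, length(set$pathogenic_scores) +
                                         length(set$benign_scores)),
                                 min_class = rule$min_class,
                                 grid_size = rule$grid_size,
                                 B = B, seed = seed)),
            class = "posterior_curve")
}

curve_grid <- function(set, rule) {
  pooled <- c(set$pathogenic_scores, set$benign_scores)
  lo <- min(pooled); hi <- max(pooled)
  if (lo == hi) return(lo)
  seq(lo, hi, length.out = rule$grid_size)
}

#' Estimate the local posterior probability curve
#'
#' Evaluates [local_posterior_at()] on an evenly spaced grid spanning the
#' pooled oriented score range. If all scores are identical the curve
#' degenerates to a single point (with a warning).
#'
#' @inheritParams local_posterior_at
#' @return A `posterior_curve` (no bootstrap bounds yet).
#' @export
estimate_posterior_curve <- function(set, prior, rule = window_rule()) {
  set <- ensure_oriented(set)
  if (!is_fraction(prior, open = TRUE))
    abort_input("`prior` must lie strictly inside (0, 1)")
  grid <- curve_grid(set, rule)
  if (length(grid) == 1L)
    warning("degenerate score range: single-point posterior curve")
  sp <- sort(set$pathogenic_scores); sb <- sort(set$benign_scores)
  mc <- resolve_min_count(rule, length(sp) + length(sb))
  w <- local_window_counts(sp, sb, grid, mc, rule$min_class)
  est <- posterior_from_counts(w$c_path, w$c_benign, length(sp), length(sb), prior)
  new_posterior_curve(grid, est, w$half_width, w$c_path, w$c_benign,
                      set, prior, rule)
}

#' Bootstrap one-sided confidence bounds for the posterior curve
#'
#' Draws `B` bootstrap replicates, each resampling the pathogenic and benign
#' score lists independently with replacement at their original sizes and
#' recomputing the full curve including window re-selection. Per grid point,
#' `lower` is the 5th and `upper` the 95th percentile across replicates; the
#' stringent side used for threshold extraction is `lower` for pathogenic
#' levels and `upper` for benign levels (a one-sided 95% bound each way).
#'
#' @inheritParams local_posterior_at
#' @param B Number of bootstrap replicates (default 10000).
#' @param seed Integer seed (required: the bootstrap is stochastic).
#' @return A `posterior_curve` with `lower` and `upper` filled in.
#' @export
bootstrap_bounds <- function(set, prior, rule = window_rule(), B = 10000L,
                             seed) {
  if (missing(seed) || is.null(seed))
    abort_config("`seed` is required for the bootstrap")
  if (!is_count(B)) abort_config("`B` must be a count >= 1")
  set <- ensure_oriented(set)
  base <- estimate_posterior_curve(set, prior, rule)
  grid <- base$grid
  nP <- base$n_path; nB <- base$n_benign
  p <- set$pathogenic_scores; b <- set$benign_scores
  mc <- resolve_min_count(rule, nP + nB)
  reps <- with_seed(seed, {
    out <- matrix(NA_real_, length(grid), B)
    for (r in seq_len(B)) {
      sp <- sort(p[sample.int(nP, nP, replace = TRUE)])
      sb <- sort(b[sample.int(nB, nB, replace = TRUE)])
      w <- local_window_counts(sp, sb, grid, mc, rule$min_class)
      out[, r] <- posterior_from_counts(w$c_path, w$c_benign, nP, nB, prior)
    }
    out
  })
  qs <- t(apply(reps, 1L, stats::quantile, probs = c(0.05, 0.95),
                na.rm = TRUE, names = FALSE))
  new_posterior_curve(grid, base$estimate, base$half_width, base$c_path,
                      base$c_benign, set, prior, rule,
                      lower = qs[, 1], upper = qs[, 2], B = B, seed = seed)
}

new_evidence_thresholds <- function(tool, variant_type, direction, prior,
                                    levels, settings = list()) {
  structure(list(tool = tool, variant_type = variant_type,
                 direction = direction, prior = prior,
                 levels = levels, settings = settings),
            class = "evidence_thresholds")
}

#' @export
print.evidence_thresholds <- function(x, ...) {
  cat(sprintf("<evidence_thresholds> %s / %s (%s), prior = %s\n",
              x$tool, x$variant_type, x$direction,
              format(x$prior %||% NA)))
  if (nrow(x$levels) == 0L) { cat("  no evidence level attained\n"); return(invisible(x)) }
  tab <- x$levels
  tab$interval <- interval_string(tab)
  print(tab[, c("level", "interval", "support_n", "excluded_reason")],
        row.names = FALSE)
  invisible(x)
}

interval_string <- function(tab) {
  mapply(function(lo, hi, li, hi_in) {
    l <- if (is.finite(lo)) format(signif(lo, 6)) else "-Inf"
    h <- if (is.finite(hi)) format(signif(hi, 6)) else "Inf"
    paste0(if (li) "[" else "(", l, ", ", h, if (hi_in) "]" else ")")
  }, tab$interval_low, tab$interval_high, tab$low_inclusive, tab$high_inclusive)
}

# Map an oriented half-open interval [lo, hi) / (lo, hi] etc. back to the
# tool's native axis. Negation swaps ends and flips inclusivity.
deorient_interval <- function(lo, hi, lo_inc, hi_inc, direction) {
  if (direction == "higher_pathogenic")
    return(list(lo = lo, hi = hi, lo_inc = lo_inc, hi_inc = hi_inc))
  list(lo = -hi, hi = -lo, lo_inc = hi_inc, hi_inc = lo_inc)
}

#' Extract per-level score thresholds from a bounded posterior curve
#'
#' For pathogenic level +k the threshold is the least oriented grid score t
#' such that the stringent lower bound stays at or above the level's
#' posterior bound for every grid point at or beyond t; for benign level -k
#' it is the greatest t below which the upper bound never exceeds the
#' level's posterior ceiling. A level at the extremes of the score
#' distribution is reported only if at least `min_support` calibration
#' scores (both classes pooled) lie at or beyond its threshold; otherwise it
#' is excluded with reason `"insufficient extreme support"`. Intervals
#' between consecutive attained thresholds are emitted in the tool's
#' original units with each boundary assigned to the stronger level.
#'
#' @param curve A `posterior_curve` with bootstrap bounds.
#' @param scale A [point_scale()] whose prior equals the curve's prior.
#' @param min_support Minimum pooled calibration scores beyond a threshold
#'   (default 10).
#' @return An [`evidence_thresholds`][extract_thresholds] object; its
#'   `levels` data frame has one row per attained or support-excluded level
#'   with the interval in original units, `support_n` and `excluded_reason`.
#'   An empty `levels` table is a valid outcome.
#' @export
extract_thresholds <- function(curve, scale, min_support = 10L) {
  stopifnot(inherits(curve, "posterior_curve"), inherits(scale, "point_scale"))
  if (is.null(curve$lower) || is.null(curve$upper))
    abort_input("curve has no bootstrap bounds; run bootstrap_bounds() first")
  if (!isTRUE(all.equal(scale$prior, curve$prior)))
    abort_input("scale prior does not match curve prior")
  thresholds_from_bounds(curve, curve$lower, curve$upper, scale, min_support)
}

# Shared core so conservatism checks can also extract from the point
# estimate itself.
thresholds_from_bounds <- function(curve, lower, upper, scale, min_support) {
  grid <- curve$grid
  pooled <- curve$oriented_scores
  n_ge <- function(t) sum(pooled >= t)
  n_le <- function(t) sum(pooled <= t)

  lo_clean <- ifelse(is.na(lower), -Inf, lower)
  up_clean <- ifelse(is.na(upper), Inf, upper)
  suff_min <- rev(cummin(rev(lo_clean)))   # min of lower over u >= t
  pref_max <- cummax(up_clean)             # max of upper over u <= t

  rows <- list()
  # pathogenic levels
  t_prev <- NA_real_
  for (k in 1:4) {
    pk <- posterior_from_lr(scale$level_lr[[sprintf("%+d", k)]], scale$prior)
    idx <- which(suff_min >= pk)
    if (!length(idx)) break
    t_k <- grid[idx[1]]
    rows[[length(rows) + 1L]] <- data.frame(level = k, oriented_threshold = t_k,
                                            support_n = n_ge(t_k))
  }
  # benign levels
  for (k in 1:4) {
    pk <- posterior_from_lr(scale$level_lr[[sprintf("%+d", -k)]], scale$prior)
    idx <- which(pref_max <= pk)
    if (!length(idx)) break
    b_k <- grid[idx[length(idx)]]
    rows[[length(rows) + 1L]] <- data.frame(level = -k, oriented_threshold = b_k,
                                            support_n = n_le(b_k))
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(level = integer(), oriented_threshold = numeric(),
               support_n = integer())
  tab$excluded_reason <- ifelse(tab$support_n < min_support,
                                "insufficient extreme support", NA_character_)
  levels_df <- build_level_intervals(tab, curve$direction)
  new_evidence_thresholds(curve$tool, curve$variant_type, curve$direction,
                          curve$prior, levels_df,
                          settings = c(curve$settings,
                                       list(min_support = min_support)))
}

build_level_intervals <- function(tab, direction) {
  out <- data.frame(level = integer(), threshold = numeric(),
                    interval_low = numeric(), interval_high = numeric(),
                    low_inclusive = logical(), high_inclusive = logical(),
                    support_n = integer(), excluded_reason = character(),
                    stringsAsFactors = FALSE)
  if (!nrow(tab)) return(out)
  add_row <- function(level, thr, lo, hi, lo_inc, hi_inc, support, reason) {
    iv <- deorient_interval(lo, hi, lo_inc, hi_inc, direction)
    thr_raw <- if (direction == "higher_pathogenic") thr else -thr
    out[nrow(out) + 1L, ] <<- list(level, thr_raw, iv$lo, iv$hi,
                                   iv$lo_inc, iv$hi_inc, support, reason)
  }
  path <- tab[tab$level > 0 & is.na(tab$excluded_reason), , drop = FALSE]
  path <- path[order(path$level), , drop = FALSE]
  if (nrow(path)) {
    for (i in seq_len(nrow(path))) {
      lo <- path$oriented_threshold[i]
      hi <- if (i < nrow(path)) path$oriented_threshold[i + 1] else Inf
      # oriented [lo, hi): boundary belongs to the stronger (next) level
      add_row(path$level[i], lo, lo, hi, TRUE, FALSE,
              path$support_n[i], NA_character_)
    }
  }
  ben <- tab[tab$level < 0 & is.na(tab$excluded_reason), , drop = FALSE]
  ben <- ben[order(-ben$level), , drop = FALSE]  # -1, -2, ...
  if (nrow(ben)) {
    for (i in seq_len(nrow(ben))) {
      hi <- ben$oriented_threshold[i]
      lo <- if (i < nrow(ben)) ben$oriented_threshold[i + 1] else -Inf
      # oriented (lo, hi]: boundary lo belongs to the stronger (more
      # negative) level
      add_row(ben$level[i], hi, lo, hi, FALSE, TRUE,
              ben$support_n[i], NA_character_)
    }
  }
  exc <- tab[!is.na(tab$excluded_reason), , drop = FALSE]
  if (nrow(exc)) {
    for (i in seq_len(nrow(exc))) {
      add_row(exc$level[i], exc$oriented_threshold[i], NA_real_, NA_real_,
              NA, NA, exc$support_n[i], exc$excluded_reason[i])
    }
  }
  out[order(out$level), , drop = FALSE]
}

#' Calibrate one tool: insertions and deletions independently
#'
#' Runs the full chain (orientation, posterior curve, bootstrap bounds,
#' threshold extraction) once per variant type with its own prior; the types
#' are never pooled. A missing type yields `NULL` for that slot with a
#' warning.
#'
#' @param insertion_set,deletion_set [score_set()] objects (either may be
#'   `NULL`).
#' @param insertion_prior,deletion_prior Per-type priors in (0, 1).
#' @param rule A [window_rule()].
#' @param B,seed Bootstrap replicates and seed (see [bootstrap_bounds()]).
#' @param min_support See [extract_thresholds()].
#' @return A list with elements `insertion` and `deletion`, each a list of
#'   `thresholds` and `curve` (or `NULL`).
#' @export
calibrate_tool <- function(insertion_set = NULL, deletion_set = NULL,
                           insertion_prior = NULL, deletion_prior = NULL,
                           rule = window_rule(), B = 10000L, seed,
                           min_support = 10L) {
  run_one <- function(set, prior, what) {
    if (is.null(set)) { warning(sprintf("no %s score set supplied", what)); return(NULL) }
    if (is.null(prior)) abort_config(sprintf("missing %s prior", what))
    curve <- bootstrap_bounds(set, prior, rule, B = B, seed = seed)
    thr <- extract_thresholds(curve, point_scale(prior), min_support = min_support)
    list(thresholds = thr, curve = curve)
  }
  list(insertion = run_one(insertion_set, insertion_prior, "insertion"),
       deletion = run_one(deletion_set, deletion_prior, "deletion"))
}
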
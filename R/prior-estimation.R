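# Positive-unlabeled class-prior estimation via a nearest-neighbour
# distance curve. The unlabeled reference sample is consumed point by
# point: repeatedly draw a labeled positive at random, record the distance
# to its nearest remaining unlabeled point and remove that point. While
# positive-like unlabeled points remain the recorded distances stay small;
# once they are exhausted the curve rises. The consumed fraction at the
# rise (the knee) estimates the positive fraction alpha.

#' Standardize positive and unlabeled feature matrices jointly
#'
#' Each column is centred and scaled by the pooled (positives + unlabeled)
#' mean and standard deviation, so Euclidean distances weight features
#' comparably. Constant columns are dropped and recorded.
#'
#' @param positives,unlabeled Numeric matrices with identical column sets.
#' @return A list with standardized `positives` and `unlabeled`, plus
#'   `dropped` (names of constant columns), `center` and `scale`.
#' @export
standardize_features <- function(positives, unlabeled) {
  positives <- as.matrix(positives); unlabeled <- as.matrix(unlabeled)
  if (!is.null(colnames(positives)) || !is.null(colnames(unlabeled))) {
    if (is.null(colnames(positives)) || is.null(colnames(unlabeled)) ||
        !setequal(colnames(positives), colnames(unlabeled)))
      abort_input("positives and unlabeled must share one column set")
    unlabeled <- unlabeled[, colnames(positives), drop = FALSE]
  } else if (ncol(positives) != ncol(unlabeled)) {
    abort_input("positives and unlabeled must share one column set")
  }
  pooled <- rbind(positives, unlabeled)
  ctr <- colMeans(pooled)
  scl <- apply(pooled, 2L, stats::sd)
  keep <- scl > 1e-12
  dropped <- colnames(pooled)[!keep] %||% character(0)
  if (!any(keep)) abort_input("all feature columns are constant")
  std <- function(m) scale(m[, keep, drop = FALSE],
                           center = ctr[keep], scale = scl[keep])
  p <- std(positives); u <- std(unlabeled)
  attr(p, "scaled:center") <- attr(p, "scaled:scale") <- NULL
  attr(u, "scaled:center") <- attr(u, "scaled:scale") <- NULL
  list(positives = p, unlabeled = u, dropped = dropped,
       center = ctr[keep], scale = scl[keep])
}

#' Build the nearest-neighbour distance curve
#'
#' Per repetition: copy the unlabeled set; repeatedly draw a positive point
#' uniformly at random (with replacement), record the Euclidean distance to
#' its nearest remaining unlabeled point (ties broken by lowest row index)
#' and remove that point, until the copy is exhausted. The curve is the
#' elementwise mean over repetitions of the recorded distance sequence,
#' indexed by the consumed fraction of the unlabeled sample.
#'
#' @param positives,unlabeled Standardized feature matrices.
#' @param n_reps Number of repetitions averaged (default 100).
#' @param seed Integer seed.
#' @param keep_reps Retain the per-repetition curves (`$reps`)?
#' @return A `distance_curve` object with `fractions`, `mean_distances`,
#'   `n_reps` and optionally `reps`.
#' @export
build_distance_curve <- function(positives, unlabeled, n_reps = 100L,
                                 seed = NULL, keep_reps = FALSE) {
  positives <- as.matrix(positives); unlabeled <- as.matrix(unlabeled)
  if (nrow(positives) < 1L || nrow(unlabeled) < 1L)
    abort_input("positive and unlabeled sets must be non-empty")
  if (ncol(positives) != ncol(unlabeled))
    abort_input("feature dimensionality differs between sets")
  if (!is_count(n_reps)) abort_config("`n_reps` must be a count >= 1")
  n_unl <- nrow(unlabeled)
  draws <- with_seed(seed, matrix(sample.int(nrow(positives), n_unl * n_reps,
                                             replace = TRUE),
                                  n_unl, n_reps))
  reps <- distance_curve_reps(positives, unlabeled, draws)
  structure(list(fractions = seq_len(n_unl) / n_unl,
                 mean_distances = rowMeans(reps),
                 n_reps = n_reps,
                 reps = if (keep_reps) reps else NULL,
                 seed = seed),
            class = "distance_curve")
}

# centred moving average with edge replication; window forced odd
smooth_ma <- function(x, window) {
  n <- length(x)
  window <- max(3L, as.integer(window))
  if (window %% 2L == 0L) window <- window + 1L
  window <- min(window, if (n %% 2L == 1L) n else n - 1L)
  if (window < 3L || n < 3L) return(list(x = x, half = 0L))
  h <- (window - 1L) %/% 2L
  padded <- c(rep(x[1], h), x, rep(x[n], h))
  sm <- stats::filter(padded, rep(1 / window, window), sides = 2)
  list(x = as.numeric(sm[(h + 1L):(h + n)]), half = h)
}

#' Estimate the class prior from a distance curve
#'
#' Finds the knee of the mean distance curve: the curve is smoothed with a
#' centred moving average (window 5% of the curve length, minimum 3), first
#' differences of the smoothed curve are taken, and the knee is the first
#' position where the difference reaches half of its maximum. Because a
#' centred moving average spreads a jump uniformly over the window, the
#' smoother half-width is added back, which makes an ideal step at fraction
#' f return exactly f. A flat or non-rising curve means the unlabeled
#' sample is indistinguishable from the positives; such a curve returns
#' `alpha_hat = 1` with `degenerate = TRUE` rather than failing.
#'
#' @param curve A `distance_curve` from [build_distance_curve()].
#' @param stratum Label stored on the estimate (default `"all"`).
#' @return A `prior_estimate` list: `alpha_hat` in \[0, 1\], `stratum`,
#'   `degenerate`, `n_unl`, `settings`.
#' @export
estimate_alpha <- function(curve, stratum = "all") {
  stopifnot(inherits(curve, "distance_curve"))
  d <- curve$mean_distances
  n <- length(d)
  if (n < 2L) {
    return(structure(list(alpha_hat = 1, stratum = stratum, degenerate = TRUE,
                          n_unl = n, settings = list(n_reps = curve$n_reps)),
                     class = "prior_estimate"))
  }
  window <- max(3L, ceiling(0.05 * n))
  sm <- smooth_ma(d, window)
  g <- diff(sm$x)
  gmax <- max(g)
  if (!is.finite(gmax) || gmax <= 1e-12) {
    return(structure(list(alpha_hat = 1, stratum = stratum, degenerate = TRUE,
                          n_unl = n, settings = list(n_reps = curve$n_reps,
                                                     window = window)),
                     class = "prior_estimate"))
  }
  i_star <- which(g >= gmax / 2)[1]
  # add the smoother half-width back: a centred moving average makes a step
  # at index m first register in the differences at m - half
  idx <- min(n, i_star + sm$half)
  alpha <- min(1, max(0, curve$fractions[idx]))
  structure(list(alpha_hat = alpha, stratum = stratum, degenerate = FALSE,
                 n_unl = n,
                 settings = list(n_reps = curve$n_reps, window = window,
                                 seed = curve$seed)),
            class = "prior_estimate")
}

#' @export
print.prior_estimate <- function(x, ...) {
  cat(sprintf("<prior_estimate> stratum = %s, alpha_hat = %.4f%s (n_unl = %d)\n",
              x$stratum, x$alpha_hat,
              if (x$degenerate) " [degenerate]" else "", x$n_unl))
  invisible(x)
}

#' Estimate the prior overall and per variant-type stratum
#'
#' Runs standardization, distance-curve construction and knee estimation on
#' the full data and on the insertion-only and deletion-only subsets
#' (positives and unlabeled subset to the matching stratum). An empty
#' stratum is skipped with a warning.
#'
#' @param positives,unlabeled Raw feature matrices.
#' @param pos_strata,unl_strata Character vectors (`"insertion"` /
#'   `"deletion"`) labelling rows; `NULL` for an unstratified run only.
#' @param n_reps,seed Passed to [build_distance_curve()].
#' @return A named list of `prior_estimate` objects (`all`, and any stratum
#'   with data on both sides).
#' @export
estimate_priors_stratified <- function(positives, unlabeled,
                                       pos_strata = NULL, unl_strata = NULL,
                                       n_reps = 100L, seed = NULL) {
  run <- function(p, u, label) {
    std <- standardize_features(p, u)
    crv <- build_distance_curve(std$positives, std$unlabeled,
                                n_reps = n_reps, seed = seed)
    estimate_alpha(crv, stratum = label)
  }
  out <- list(all = run(positives, unlabeled, "all"))
  if (!is.null(unl_strata)) {
    if (is.null(pos_strata))
      abort_input("stratified estimation needs strata labels for both samples")
    if (length(unl_strata) != nrow(unlabeled) ||
        length(pos_strata) != nrow(positives))
      abort_input("strata labels must match matrix rows")
    for (st in c("insertion", "deletion")) {
      pi <- pos_strata == st; ui <- unl_strata == st
      if (!any(pi) || !any(ui)) {
        warning(sprintf("stratum '%s' empty on one side; skipped", st))
        next
      }
      out[[st]] <- run(positives[pi, , drop = FALSE],
                       unlabeled[ui, , drop = FALSE], st)
    }
  }
  out
}
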
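# Point-based Bayesian evidence framework. Evidence strength is counted in
# signed points k (supporting = +/-1, moderate = +/-2, strong = +/-4); k
# points correspond to a likelihood ratio s^k, where the per-point LR s is
# anchored so that six points of pathogenic evidence reach exactly the
# likely-pathogenic posterior floor of 0.90 at the given prior.

#' Posterior probability from a likelihood ratio and prior (Bayes odds update)
#'
#' @param lr Non-negative likelihood ratio(s).
#' @param prior Prior probability of pathogenicity, strictly inside (0, 1).
#' @return `lr * prior / (lr * prior + (1 - prior))`, strictly increasing in
#'   `lr`.
#' @examples
#' posterior_from_lr(1, 0.046)       # uninformative evidence returns the prior
#' posterior_from_lr(186.65, 0.046)  # ~0.90, six supporting points
#' @export
posterior_from_lr <- function(lr, prior) {
  if (!is.numeric(prior) || length(prior) < 1L || anyNA(prior) ||
      any(prior <= 0 | prior >= 1))
    abort_input("`prior` must lie strictly inside (0, 1)")
  if (any(!is.na(lr) & lr < 0)) abort_input("`lr` must be non-negative")
  lr * prior / (lr * prior + (1 - prior))
}

#' Per-point likelihood ratio for a given prior
#'
#' Solves `posterior_from_lr(s^6, prior) = 0.90` in closed form:
#' `s = (9 * (1 - prior) / prior)^(1/6)`. Six points is the likely-pathogenic
#' floor, so s is the multiplicative LR value of a single evidence point.
#' For priors >= 0.9 the solution has s <= 1 and the scale is degenerate
#' (evidence points would not raise the posterior); such calls carry a
#' `degenerate` attribute rather than failing.
#'
#' @param prior Prior probability of pathogenicity in (0, 1).
#' @return The per-point likelihood ratio s (> 1 for priors < 0.9).
#' @examples
#' round(per_point_lr(0.046), 2)  # 2.39
#' round(per_point_lr(0.10), 2)   # 2.08 (historical prior; odds constant ~350)
#' @export
per_point_lr <- function(prior) {
  if (!is_fraction(prior, open = TRUE))
    abort_input("`prior` must lie strictly inside (0, 1)")
  s <- (9 * (1 - prior) / prior)^(1 / 6)
  if (prior >= 0.9) attr(s, "degenerate") <- TRUE
  s
}

check_level <- function(k) {
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k != trunc(k) ||
      k == 0 || abs(k) > 4)
    abort_input("evidence level k must be in {-4..-1, +1..+4}")
  as.integer(k)
}

#' Expected minimum likelihood ratio for an evidence level
#'
#' `s^k` for level `k`: for pathogenic levels (k > 0) this is the minimum LR
#' the evidence must carry; for benign levels (k < 0) the value is below 1
#' and acts as an upper bound whose reciprocal is the reported inverse LR.
#'
#' @param prior Prior probability of pathogenicity in (0, 1).
#' @param k Signed evidence level in `{-4..-1, +1..+4}`.
#' @return The LR bound `per_point_lr(prior)^k`.
#' @examples
#' round(expected_lr_for_level(0.046, +1), 2)  # 2.39
#' round(expected_lr_for_level(0.046, +2), 2)  # 5.71 = 2.39^2 before rounding
#' @export
expected_lr_for_level <- function(prior, k) {
  k <- check_level(k)
  as.numeric(per_point_lr(prior))^k
}

#' Posterior-probability bound for an evidence level
#'
#' The local posterior a score region must reach to support level `k`:
#' a lower bound for pathogenic levels, an upper bound for benign levels.
#'
#' @inheritParams expected_lr_for_level
#' @return `posterior_from_lr(expected_lr_for_level(prior, k), prior)`.
#' @export
posterior_threshold_for_level <- function(prior, k) {
  posterior_from_lr(expected_lr_for_level(prior, k), prior)
}

#' Build the full point scale for a prior
#'
#' @param prior Prior probability of pathogenicity in (0, 1).
#' @return An object of class `point_scale` with elements `prior`,
#'   `per_point_lr`, `level_lr` and `level_posterior` (named by level
#'   `-4..+4` excluding 0), `odds_constant` (`s^8`, the framework's
#'   very-strong odds of pathogenicity) and a `degenerate` flag.
#' @examples
#' ps <- point_scale(0.046)
#' ps$level_lr[["+1"]]
#' @export
point_scale <- function(prior) {
  s <- per_point_lr(prior)
  degenerate <- isTRUE(attr(s, "degenerate"))
  s <- as.numeric(s)
  ks <- c(-4:-1, 1:4)
  lev <- sprintf("%+d", ks)
  level_lr <- stats::setNames(s^ks, lev)
  level_post <- stats::setNames(posterior_from_lr(s^ks, prior), lev)
  structure(list(prior = prior, per_point_lr = s, level_lr = level_lr,
                 level_posterior = level_post, odds_constant = s^8,
                 degenerate = degenerate),
            class = "point_scale")
}

#' @export
print.point_scale <- function(x, ...) {
  cat(sprintf("<point_scale> prior = %.4g, per-point LR s = %.4f%s\n",
              x$prior, x$per_point_lr,
              if (x$degenerate) " (degenerate)" else ""))
  tab <- data.frame(level = names(x$level_lr),
                    expected_lr = round(x$level_lr, 2),
                    posterior_bound = round(x$level_posterior, 4))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Consistency report for a point scale
#'
#' Checks the scale against the ACMG/AMP posterior anchors: ten points of
#' pathogenic evidence must reach the pathogenic floor (posterior >= 0.99),
#' six points must sit exactly at the likely-pathogenic floor (0.90), and
#' minus six points must fall at or below the likely-benign ceiling (0.10).
#' A degenerate scale (prior >= 0.9) is flagged, never an error.
#'
#' @param scale A [point_scale()] object.
#' @return A data frame with one row per rule: `rule`, `value`, `pass`.
#' @export
validate_point_scale <- function(scale) {
  stopifnot(inherits(scale, "point_scale"))
  s <- scale$per_point_lr; a <- scale$prior
  p10 <- posterior_from_lr(s^10, a)
  p6 <- posterior_from_lr(s^6, a)
  pm6 <- posterior_from_lr(s^-6, a)
  data.frame(
    rule = c("pathogenic_floor_10pt", "likely_pathogenic_6pt",
             "likely_benign_minus6pt", "non_degenerate"),
    value = c(p10, p6, pm6, s),
    pass = c(p10 >= 0.99, abs(p6 - 0.90) < 1e-9, pm6 <= 0.10,
             !scale$degenerate),
    stringsAsFactors = FALSE)
}
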
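#' Specify a class-conditional score distribution
#'
#' Describes the distribution of predictor scores within one class
#' (pathogenic or benign). Three families are supported: `"gaussian"`
#' (unbounded scores, e.g. log-likelihood-ratio outputs), `"beta"`
#' (probability-like scores on \[0, 1\]) and `"mixture"` of either.
#'
#' @param family One of `"gaussian"`, `"beta"`, `"mixture"`.
#' @param params For `"gaussian"`: `list(mean =, sd =)`. For `"beta"`:
#'   `list(shape1 =, shape2 =)`. For `"mixture"`: a list of components, each
#'   `list(weight =, spec = <score_dist_spec>)`; weights must be positive and
#'   sum to 1.
#'
#' @return An object of class `score_dist_spec` with a finite `support` for
#'   beta specs and an unbounded support for gaussian specs.
#' @examples
#' score_dist_spec("gaussian", list(mean = 2, sd = 1))
#' score_dist_spec("beta", list(shape1 = 5, shape2 = 2))
#' @export
score_dist_spec <- function(family = c("gaussian", "beta", "mixture"), params) {
  family <- match.arg(family)
  if (family == "gaussian") {
    if (!is.numeric(params$mean) || !is.numeric(params$sd) || params$sd <= 0)
      abort_config("gaussian spec needs numeric `mean` and positive `sd`")
    support <- c(-Inf, Inf)
  } else if (family == "beta") {
    if (!is.numeric(params$shape1) || !is.numeric(params$shape2) ||
        params$shape1 <= 0 || params$shape2 <= 0)
      abort_config("beta spec needs positive `shape1` and `shape2`")
    support <- c(0, 1)
  } else {
    if (!is.list(params) || length(params) < 1L)
      abort_config("mixture spec needs a non-empty component list")
    w <- vapply(params, function(p) p$weight, numeric(1))
    if (any(w <= 0) || abs(sum(w) - 1) > 1e-8)
      abort_config("mixture weights must be positive and sum to 1")
    for (p in params) {
      if (!inherits(p$spec, "score_dist_spec"))
        abort_config("each mixture component needs a `spec` of class score_dist_spec")
    }
    sup <- vapply(params, function(p) p$spec$support, numeric(2))
    support <- c(min(sup[1, ]), max(sup[2, ]))
  }
  structure(list(family = family, params = params, support = support),
            class = "score_dist_spec")
}

# Density of a score_dist_spec at x (vectorised).
dscore <- function(spec, x) {
  switch(spec$family,
    gaussian = stats::dnorm(x, spec$params$mean, spec$params$sd),
    beta     = stats::dbeta(x, spec$params$shape1, spec$params$shape2),
    mixture  = {
      out <- numeric(length(x))
      for (p in spec$params) out <- out + p$weight * dscore(p$spec, x)
      out
    })
}

# Random draws from a score_dist_spec; relies on the current RNG stream.
rscore <- function(spec, n) {
  switch(spec$family,
    gaussian = stats::rnorm(n, spec$params$mean, spec$params$sd),
    beta     = stats::rbeta(n, spec$params$shape1, spec$params$shape2),
    mixture  = {
      w <- vapply(spec$params, function(p) p$weight, numeric(1))
      comp <- sample.int(length(w), n, replace = TRUE, prob = w)
      out <- numeric(n)
      for (i in seq_along(spec$params)) {
        idx <- which(comp == i)
        if (length(idx)) out[idx] <- rscore(spec$params[[i]]$spec, length(idx))
      }
      out
    })
}

#' Ground truth for a synthetic two-class score population
#'
#' Bundles the pathogenic and benign score distributions with the prior
#' probability of pathogenicity, so the exact posterior
#' \eqn{\alpha f_P(s) / (\alpha f_P(s) + (1-\alpha) f_B(s))} is available as
#' an analytic oracle for any downstream estimate.
#'
#' @param pathogenic_spec,benign_spec [score_dist_spec()] objects.
#' @param prior Prior probability of pathogenicity, strictly inside (0, 1).
#' @param seed Integer seed attached to the truth object; generators draw
#'   from it.
#' @return An object of class `synthetic_truth`.
#' @examples
#' tr <- synthetic_truth(
#'   score_dist_spec("gaussian", list(mean = 2, sd = 1)),
#'   score_dist_spec("gaussian", list(mean = 0, sd = 1)),
#'   prior = 0.046, seed = 1)
#' analytic_posterior(tr, 1)  # equals the prior at the midpoint
#' @export
synthetic_truth <- function(pathogenic_spec, benign_spec, prior, seed = NULL) {
  if (!inherits(pathogenic_spec, "score_dist_spec") ||
      !inherits(benign_spec, "score_dist_spec"))
    abort_config("both class specs must be score_dist_spec objects")
  if (!is_fraction(prior, open = TRUE))
    abort_config("`prior` must lie strictly inside (0, 1)")
  structure(list(pathogenic_spec = pathogenic_spec, benign_spec = benign_spec,
                 prior = prior, seed = seed),
            class = "synthetic_truth")
}

#' Exact posterior probability of pathogenicity under a synthetic truth
#'
#' @param truth A [synthetic_truth()] object.
#' @param s Numeric vector of scores.
#' @return Posterior probabilities in \[0, 1\]; `NaN` where both class
#'   densities vanish.
#' @export
analytic_posterior <- function(truth, s) {
  stopifnot(inherits(truth, "synthetic_truth"))
  a <- truth$prior
  num <- a * dscore(truth$pathogenic_spec, s)
  den <- num + (1 - a) * dscore(truth$benign_spec, s)
  num / den
}
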
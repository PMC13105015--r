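#' Paired pathogenic/benign score samples for one tool and variant type
#'
#' The unit of calibration: all pathogenic and all benign scores of a single
#' predictor on a single variant type, together with the declared score
#' direction. Direction is never inferred from the data; predictors disagree
#' on polarity (probability-like tools score pathogenic variants high,
#' log-likelihood-ratio tools score them low).
#'
#' @param pathogenic_scores,benign_scores Non-empty finite numeric vectors.
#' @param tool Tool name (free text).
#' @param variant_type `"insertion"` or `"deletion"`.
#' @param direction `"higher_pathogenic"` or `"lower_pathogenic"`.
#' @param truth Optional [synthetic_truth()] carried along for oracle checks.
#' @return An object of class `score_set`.
#' @export
score_set <- function(pathogenic_scores, benign_scores, tool = "tool",
                      variant_type = c("deletion", "insertion"),
                      direction = c("higher_pathogenic", "lower_pathogenic"),
                      truth = NULL) {
  variant_type <- match.arg(variant_type)
  direction <- match.arg(direction)
  if (length(pathogenic_scores) < 1L || length(benign_scores) < 1L)
    abort_input("both score lists must be non-empty")
  if (!all(is.finite(pathogenic_scores)) || !all(is.finite(benign_scores)))
    abort_input("scores must be finite")
  structure(list(tool = tool, variant_type = variant_type,
                 direction = direction,
                 pathogenic_scores = as.numeric(pathogenic_scores),
                 benign_scores = as.numeric(benign_scores),
                 oriented = FALSE, truth = truth),
            class = "score_set")
}

#' @export
print.score_set <- function(x, ...) {
  cat(sprintf("<score_set> %s / %s (%s%s)\n  n_pathogenic = %d, n_benign = %d\n",
              x$tool, x$variant_type, x$direction,
              if (isTRUE(x$oriented)) ", oriented" else "",
              length(x$pathogenic_scores), length(x$benign_scores)))
  invisible(x)
}
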
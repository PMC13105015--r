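# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

#' @useDynLib indelcal, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Two error families, so callers (and the command-line wrapper) can
# distinguish a bad configuration from bad input data.
abort_config <- function(msg, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c("indelcal_config_error", "indelcal_error"),
                      call = call))
}

abort_input <- function(msg, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c("indelcal_input_error", "indelcal_error"),
                      call = call))
}

# Evaluate `expr` under `seed` without touching the caller's RNG stream.
# All stochastic entry points funnel through this, so no function leaves
# global RNG state behind.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort_config("`seed` must be a single non-missing integer")
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= min && x == trunc(x)
}

is_fraction <- function(x, open = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x)
  if (!ok) return(FALSE)
  if (open) x > 0 && x < 1 else x >= 0 && x <= 1
}

`%||%` <- function(a, b) if (is.null(a)) b else a
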
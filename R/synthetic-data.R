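# Synthetic-data module: every input the pipeline consumes, generated with
# known ground truth. These generators are first-class, tested code; the
# defaults encode the study conditions the calibration emulates.

#' Draw a two-class score sample from a synthetic truth
#'
#' Samples pathogenic and benign scores independently from the
#' class-conditional distributions of `truth`, returning a [score_set()] that
#' retains the truth object so the analytic posterior is computable at any
#' score.
#'
#' @param truth A [synthetic_truth()] object.
#' @param n_path,n_benign Class sample sizes (at least 1).
#' @param tool,variant_type,direction Passed to [score_set()].
#' @param seed Seed; defaults to the seed stored in `truth`.
#' @return A [score_set()] with `truth` attached.
#' @examples
#' tr <- synthetic_truth(
#'   score_dist_spec("gaussian", list(mean = 2, sd = 1)),
#'   score_dist_spec("gaussian", list(mean = 0, sd = 1)),
#'   prior = 0.046, seed = 7)
#' ss <- gen_two_class_scores(tr, 100, 100)
#' @export
gen_two_class_scores <- function(truth, n_path, n_benign, tool = "synthetic",
                                 variant_type = "deletion",
                                 direction = "higher_pathogenic",
                                 seed = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (!is_count(n_path) || !is_count(n_benign))
    abort_config("`n_path` and `n_benign` must be counts >= 1")
  seed <- seed %||% truth$seed
  if (is.null(seed)) abort_config("a seed is required (argument or truth$seed)")
  with_seed(seed, {
    p <- rscore(truth$pathogenic_spec, n_path)
    b <- rscore(truth$benign_spec, n_benign)
    score_set(p, b, tool = tool, variant_type = variant_type,
              direction = direction, truth = truth)
  })
}

#' Generate positive and unlabeled feature matrices with a planted class prior
#'
#' Emulates positive-unlabeled prior estimation input: a labeled positive
#' sample and an unlabeled sample in which a fraction `true_alpha` comes from
#' the positive component. Negative-component features are standard normal;
#' the positive component is shifted by `separation` along every axis.
#'
#' @param true_alpha Planted positive fraction of the unlabeled sample, in
#'   \[0, 1\].
#' @param n_pos,n_unl Sample sizes; `n_unl` must be at least 1.
#' @param dim Feature dimensionality (>= 1).
#' @param separation Non-negative per-axis mean shift between components.
#' @param seed Integer seed.
#' @param mode `"exact"` plants exactly `round(true_alpha * n_unl)` positives
#'   (sharp recovery tests); `"binomial"` draws the planted count from
#'   Binomial(`n_unl`, `true_alpha`).
#' @return A list with `positives` and `unlabeled` matrices, the logical
#'   vector `unlabeled_is_positive` of planted component labels, and
#'   `n_planted`.
#' @export
gen_pu_features <- function(true_alpha, n_pos, n_unl, dim = 5, separation = 3,
                            seed = NULL, mode = c("exact", "binomial")) {
  mode <- match.arg(mode)
  if (!is_fraction(true_alpha, open = FALSE))
    abort_config("`true_alpha` must lie in [0, 1]")
  if (!is_count(n_unl)) abort_config("`n_unl` must be a count >= 1")
  if (!is_count(n_pos)) abort_config("`n_pos` must be a count >= 1")
  if (!is_count(dim)) abort_config("`dim` must be a count >= 1")
  if (!is.numeric(separation) || separation < 0)
    abort_config("`separation` must be non-negative")
  with_seed(seed, {
    n_planted <- if (mode == "exact") as.integer(round(true_alpha * n_unl))
                 else stats::rbinom(1L, n_unl, true_alpha)
    pos <- matrix(stats::rnorm(n_pos * dim, mean = separation), n_pos, dim)
    lab <- rep(FALSE, n_unl)
    if (n_planted > 0L) lab[sample.int(n_unl, n_planted)] <- TRUE
    unl <- matrix(stats::rnorm(n_unl * dim), n_unl, dim)
    unl[lab, ] <- unl[lab, ] + separation
    colnames(pos) <- colnames(unl) <- paste0("f", seq_len(dim))
    list(positives = pos, unlabeled = unl,
         unlabeled_is_positive = lab, n_planted = n_planted,
         settings = list(true_alpha = true_alpha, dim = dim,
                         separation = separation, mode = mode, seed = seed))
  })
}

# The clinical filter chain, as plain predicate vectors over a variant table.
# Used both by gen_filter_fixture (to plant the expected audit) and by the
# test-suite brute-force oracle.
clinical_rule_matrix <- function(records) {
  net <- nchar(records$alt_allele) - nchar(records$ref_allele)
  cbind(
    gene_validity  = records$gene_validity %in% c("definitive", "strong", "moderate"),
    review_status  = records$review_stars >= 1L & !records$has_conflict,
    allele_freq    = is.na(records$allele_freq) | records$allele_freq <= 0.01,
    length         = abs(net) <= 50L,
    classification = records$classification %in% c("P", "P/LP", "LP", "B", "B/LB", "LB"),
    in_frame       = net %% 3L == 0L & net != 0L
  )
}

rand_alleles <- function(n, net) {
  # random ACGT strings with the requested net length changes
  base <- c("A", "C", "G", "T")
  ref_len <- pmax(1L, -net + sample.int(4L, n, replace = TRUE))
  alt_len <- ref_len + net
  mk <- function(len) vapply(len, function(l)
    paste(sample(base, l, replace = TRUE), collapse = ""), character(1))
  list(ref = mk(ref_len), alt = mk(alt_len))
}

#' Generate a variant table with planted filter outcomes
#'
#' Emits `n` variant records whose fields exercise every rule of the clinical
#' filter chain (gene validity tier, review status/conflicts, allele
#' frequency, indel length, classification, reading frame), together with the
#' planted per-rule pass/fail matrix and the expected sequential audit.
#'
#' @param n Number of records (>= 1).
#' @param seed Integer seed.
#' @return A list with `records` (data frame), `rule_pass` (logical matrix,
#'   one column per rule) and `expected_audit` (a `filter_audit` giving the
#'   count surviving each rule in order and the final kept count).
#' @export
gen_filter_fixture <- function(n, seed = NULL) {
  if (!is_count(n)) abort_config("`n` must be a count >= 1")
  with_seed(seed, {
    net_pool <- c(-60L, -48L, -9L, -6L, -3L, -2L, -1L, 0L, 1L, 2L, 3L, 6L, 9L,
                  12L, 51L, 60L)
    net <- sample(net_pool, n, replace = TRUE)
    al <- rand_alleles(n, net)
    records <- data.frame(
      variant_id = sprintf("var%05d", seq_len(n)),
      assembly = "GRCh38",
      chrom = sample(c(as.character(1:22), "X"), n, replace = TRUE),
      pos = sample.int(2e8L, n, replace = TRUE),
      ref_allele = al$ref,
      alt_allele = al$alt,
      gene = sprintf("GENE%03d", sample.int(200L, n, replace = TRUE)),
      gene_validity = sample(c("definitive", "strong", "moderate", "limited",
                               "other", "none"), n, replace = TRUE,
                             prob = c(0.4, 0.15, 0.15, 0.1, 0.1, 0.1)),
      consequence = sample(c("inframe_insertion", "inframe_deletion",
                             "complex_inframe", "other"), n, replace = TRUE),
      classification = sample(c("P", "P/LP", "LP", "B", "B/LB", "LB", "VUS",
                                "conflicting", "none"), n, replace = TRUE,
                              prob = c(rep(0.13, 6), 0.1, 0.06, 0.06)),
      review_stars = sample(0:4, n, replace = TRUE, prob = c(0.2, 0.4, 0.2, 0.15, 0.05)),
      has_conflict = sample(c(TRUE, FALSE), n, replace = TRUE, prob = c(0.15, 0.85)),
      allele_freq = ifelse(stats::runif(n) < 0.3, NA_real_,
                           round(stats::rbeta(n, 0.3, 8) * 0.05, 6)),
      qc_pass = sample(c(TRUE, FALSE), n, replace = TRUE, prob = c(0.85, 0.15)),
      genotype_quality = ifelse(stats::runif(n) < 0.1, NA_integer_,
                                sample(20:99, n, replace = TRUE)),
      depth = ifelse(stats::runif(n) < 0.1, NA_integer_,
                     sample(5:60, n, replace = TRUE)),
      allele_balance = ifelse(stats::runif(n) < 0.1, NA_real_,
                              round(stats::runif(n, 0.05, 0.6), 3)),
      stringsAsFactors = FALSE
    )
    rule_pass <- clinical_rule_matrix(records)
    # sequential audit: survivors after each rule applied in chain order
    alive <- rep(TRUE, n)
    n_in <- n_kept <- integer(ncol(rule_pass))
    for (j in seq_len(ncol(rule_pass))) {
      n_in[j] <- sum(alive)
      alive <- alive & rule_pass[, j]
      n_kept[j] <- sum(alive)
    }
    audit <- new_filter_audit(colnames(rule_pass), n_in, n_kept)
    list(records = records, rule_pass = rule_pass, expected_audit = audit)
  })
}

#' Generate a proband cohort with planted per-level variant counts
#'
#' For each proband, draws a number of variants per evidence level from the
#' requested count distribution and emits scores guaranteed to fall inside
#' that level's threshold interval, so cohort summaries have an exact
#' counting oracle.
#'
#' @param n_probands Number of probands (>= 1).
#' @param planted_level_counts Named list mapping evidence level (e.g. `"+1"`,
#'   `"0"`, `"-2"`) to either a fixed integer count per proband or a
#'   function `f(n)` returning `n` integer counts.
#' @param thresholds An [evidence_thresholds] object; every requested
#'   non-zero level must be attained in it.
#' @param seed Integer seed.
#' @return A list with `scores` (data frame: proband_id, variant_id,
#'   variant_type, score) and `planted` (data frame of per-proband per-level
#'   counts).
#' @export
gen_proband_cohort <- function(n_probands, planted_level_counts, thresholds,
                               seed = NULL) {
  if (!is_count(n_probands)) abort_config("`n_probands` must be a count >= 1")
  stopifnot(inherits(thresholds, "evidence_thresholds"))
  lev_req <- names(planted_level_counts)
  if (is.null(lev_req)) abort_config("`planted_level_counts` must be named by level")
  lev_int <- suppressWarnings(as.integer(lev_req))
  if (anyNA(lev_int)) abort_config("level names must be integers like '-2', '0', '+1'")
  attained <- thresholds$levels$level[is.na(thresholds$levels$excluded_reason)]
  missing_lev <- setdiff(lev_int[lev_int != 0L], attained)
  if (length(missing_lev))
    abort_config(sprintf("requested level(s) %s absent from thresholds",
                         paste(sprintf("%+d", missing_lev), collapse = ", ")))
  with_seed(seed, {
    planted <- data.frame(proband_id = sprintf("PB%04d", seq_len(n_probands)))
    rows <- list()
    vid <- 0L
    for (i in seq_along(lev_req)) {
      lev <- lev_int[i]
      spec <- planted_level_counts[[i]]
      counts <- if (is.function(spec)) as.integer(spec(n_probands))
                else rep(as.integer(spec), n_probands)
      if (any(counts < 0L)) abort_config("planted counts must be non-negative")
      planted[[lev_req[i]]] <- counts
      tot <- sum(counts)
      if (tot > 0L) {
        sc <- sample_scores_in_level(thresholds, lev, tot)
        rows[[length(rows) + 1L]] <- data.frame(
          proband_id = rep(planted$proband_id, counts),
          variant_id = sprintf("cv%06d", vid + seq_len(tot)),
          variant_type = thresholds$variant_type,
          score = sc, level_planted = lev,
          stringsAsFactors = FALSE)
        vid <- vid + tot
      }
    }
    scores <- if (length(rows)) do.call(rbind, rows) else
      data.frame(proband_id = character(), variant_id = character(),
                 variant_type = character(), score = numeric(),
                 level_planted = integer())
    scores <- scores[order(scores$proband_id, scores$variant_id), , drop = FALSE]
    rownames(scores) <- NULL
    list(scores = scores, planted = planted)
  })
}

# Draw n scores in original units that assign_points() maps to `level`.
sample_scores_in_level <- function(thresholds, level, n) {
  reg <- level_region(thresholds, level)
  lo <- reg[1]; hi <- reg[2]
  if (!is.finite(lo) && !is.finite(hi))
    abort_config(sprintf("level %+d has no representable score region", level))
  if (!is.finite(lo)) { lo <- hi - 2 }
  if (!is.finite(hi)) { hi <- lo + 2 }
  pad <- (hi - lo) * 0.05
  if (pad <= 0) return(rep(lo, n))
  sc <- stats::runif(n, lo + pad, hi - pad)
  lev_chk <- vapply(sc, function(s) assign_points(s, thresholds)$level, integer(1))
  if (any(lev_chk != level)) abort_config("internal: sampled score missed its level region")
  sc
}

# Raw-axis open region (lo, hi) whose interior maps to `level` (0 = gap).
level_region <- function(thresholds, level) {
  tab <- thresholds$levels[is.na(thresholds$levels$excluded_reason), , drop = FALSE]
  if (level != 0L) {
    row <- tab[tab$level == level, , drop = FALSE]
    if (nrow(row) != 1L) abort_config(sprintf("level %+d not attained", level))
    return(c(row$interval_low, row$interval_high))
  }
  # indeterminate gap: between the weakest benign and weakest pathogenic
  # intervals on the raw axis (orientation already encoded in the intervals)
  ben <- tab[tab$level < 0L, , drop = FALSE]
  pat <- tab[tab$level > 0L, , drop = FALSE]
  covered_lo <- c(ben$interval_low, pat$interval_low)
  covered_hi <- c(ben$interval_high, pat$interval_high)
  if (!nrow(tab)) return(c(-Inf, Inf))
  # the gap is the widest uncovered open interval between covered pieces
  pieces <- cbind(covered_lo, covered_hi)
  pieces <- pieces[order(pieces[, 1]), , drop = FALSE]
  gaps <- cbind(utils::head(pieces[, 2], -1), utils::tail(pieces[, 1], -1))
  gaps <- rbind(c(-Inf, min(pieces[, 1])), gaps, c(max(pieces[, 2]), Inf))
  width <- gaps[, 2] - gaps[, 1]
  ok <- which(width > 0)
  if (!length(ok)) abort_config("thresholds leave no indeterminate region")
  finite <- ok[is.finite(width[ok])]
  pick <- if (length(finite)) finite[which.max(width[finite])] else ok[1]
  gaps[pick, ]
}
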
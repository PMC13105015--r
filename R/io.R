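# Delimited-text interfaces. All pipeline files are plain TSV with named
# headers; provenance and audits are JSON.

#' Read / write a score table
#'
#' Columns: `variant_id`, `variant_type` (insertion|deletion), `label`
#' (pathogenic|benign, optional for unlabeled sets), `score`; cohort tables
#' add `proband_id`.
#'
#' @param path File path.
#' @return A data frame.
#' @export
read_score_tsv <- function(path) {
  if (!file.exists(path)) abort_input(sprintf("score file not found: %s", path))
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("variant_id", "variant_type", "score")
  if (!all(need %in% names(d)))
    abort_input(sprintf("score table must have columns %s",
                        paste(need, collapse = ", ")))
  d
}

#' @rdname read_score_tsv
#' @param scores Data frame to write.
#' @export
write_score_tsv <- function(scores, path) {
  utils::write.table(scores, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write a variant table
#'
#' Tab-separated with a named header matching the variant-record fields
#' consumed by the filters ([filter_clinical()] and friends).
#'
#' @param path File path.
#' @return A data frame.
#' @export
read_variant_tsv <- function(path) {
  if (!file.exists(path)) abort_input(sprintf("variant file not found: %s", path))
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(chrom = "character"))
}

#' @rdname read_variant_tsv
#' @param records Data frame to write.
#' @export
write_variant_tsv <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Serialize evidence thresholds to / from TSV
#'
#' One row per level: `tool`, `variant_type`, `direction`, `prior`, `level`,
#' `threshold`, `interval_low`, `interval_high`, `low_inclusive`,
#' `high_inclusive`, `support_n`, `excluded_reason`. Infinite interval ends
#' are written as `-Inf`/`Inf` and survive the round trip.
#'
#' @param thresholds An `evidence_thresholds` object.
#' @param path File path.
#' @export
write_thresholds_tsv <- function(thresholds, path) {
  tab <- thresholds$levels
  tab <- cbind(data.frame(tool = thresholds$tool,
                          variant_type = thresholds$variant_type,
                          direction = thresholds$direction,
                          prior = thresholds$prior %||% NA_real_,
                          stringsAsFactors = FALSE),
               tab)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_thresholds_tsv
#' @return `read_thresholds_tsv()` returns an `evidence_thresholds` object
#'   (or a list of them if the file holds several tool/type combinations).
#' @export
read_thresholds_tsv <- function(path) {
  if (!file.exists(path)) abort_input(sprintf("threshold file not found: %s", path))
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"excluded_reason" %in% names(d)) d$excluded_reason <- NA_character_
  d$excluded_reason[d$excluded_reason %in% c("", "NA")] <- NA_character_
  split_keys <- interaction(d$tool, d$variant_type, drop = TRUE)
  parts <- lapply(split(d, split_keys), function(g) {
    lev <- g[, c("level", "threshold", "interval_low", "interval_high",
                 "low_inclusive", "high_inclusive", "support_n",
                 "excluded_reason")]
    rownames(lev) <- NULL
    new_evidence_thresholds(g$tool[1], g$variant_type[1], g$direction[1],
                            if (is.na(g$prior[1])) NULL else g$prior[1], lev)
  })
  if (length(parts) == 1L) parts[[1]] else unname(parts)
}

#' Write a posterior curve to TSV
#'
#' Columns: `grid` (oriented scores), `estimate`, `lower`, `upper`,
#' `half_width`, `c_path`, `c_benign`.
#'
#' @param curve A `posterior_curve`.
#' @param path File path.
#' @export
write_curve_tsv <- function(curve, path) {
  d <- data.frame(grid = curve$grid, estimate = curve$estimate,
                  lower = curve$lower %||% NA_real_,
                  upper = curve$upper %||% NA_real_,
                  half_width = curve$half_width,
                  c_path = curve$c_path, c_benign = curve$c_benign)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a filter audit as JSON
#' @param audit A `filter_audit`.
#' @param path File path.
#' @export
write_audit_json <- function(audit, path) {
  jsonlite::write_json(list(rules = audit$table, final_kept = audit$final_kept),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Published evidence-threshold fixtures
#'
#' Machine-readable copies of externally published per-tool score-threshold
#' tables for in-frame deletions and insertions, shipped for
#' interval-convention tests (boundary membership, orientation). These
#' encode printed results, not values recomputed by this package.
#'
#' @param variant_type `"deletion"` or `"insertion"`.
#' @return A list of `evidence_thresholds` objects, one per tool.
#' @export
published_thresholds <- function(variant_type = c("deletion", "insertion")) {
  variant_type <- match.arg(variant_type)
  path <- system.file("extdata",
                      sprintf("published_thresholds_%s.tsv", variant_type),
                      package = "indelcal", mustWork = TRUE)
  out <- read_thresholds_tsv(path)
  if (inherits(out, "evidence_thresholds")) list(out) else out
}
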
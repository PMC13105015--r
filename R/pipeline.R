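# End-to-end orchestration: simulate -> filter -> prior -> calibrate ->
# evaluate, driven by a single flat configuration (R list or YAML file).
# Every stage reads and writes delimited text under `out_dir` and the run
# ends with a deterministic manifest (inputs, outputs, settings, digests):
# rerunning an identical configuration reproduces identical outputs.

#' Validate and normalise a pipeline run configuration
#'
#' @param config A named list, or the path of a YAML file holding one.
#'   Recognised keys: `stages` (subset of simulate, filter, prior,
#'   calibrate, evaluate), `out_dir`, `seed` (mandatory when any stochastic
#'   stage runs), `direction` (per-tool score direction, mandatory for
#'   calibrate; never inferred), `priors` (list with `insertion`,
#'   `deletion`), `bootstrap_B`, `min_count`, `grid_size`, `min_support`,
#'   stage input paths (`variants`, `scores`, `test_scores`, `features_pos`,
#'   `features_unl`, `thresholds`) and simulate sizes (`n_path`,
#'   `n_benign`).
#' @return The validated config (class `run_config`).
#' @export
run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) abort_config(sprintf("config file not found: %s", config))
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) abort_config("config must be a list or a YAML path")
  all_stages <- c("simulate", "filter", "prior", "calibrate", "evaluate")
  config$stages <- config$stages %||% all_stages
  bad <- setdiff(config$stages, all_stages)
  if (length(bad)) abort_config(sprintf("unknown stage(s): %s", paste(bad, collapse = ", ")))
  config$out_dir <- config$out_dir %||% abort_config("config needs `out_dir`")
  stochastic <- intersect(config$stages, c("simulate", "prior", "calibrate"))
  if (length(stochastic) && is.null(config$seed))
    abort_config(sprintf("`seed` is mandatory for stochastic stage(s): %s",
                         paste(stochastic, collapse = ", ")))
  if ("calibrate" %in% config$stages && is.null(config$direction))
    abort_config("calibrate stage needs `direction` (higher_pathogenic or lower_pathogenic); directions are never inferred")
  config$bootstrap_B <- config$bootstrap_B %||% 10000L
  config$grid_size <- config$grid_size %||% 1001L
  config$min_support <- config$min_support %||% 10L
  config$tool <- config$tool %||% "synthetic"
  structure(config, class = "run_config")
}

pipeline_path <- function(config, name) file.path(config$out_dir, name)

#' Run the calibration pipeline
#'
#' Executes the requested stages in dependency order. No stage mutates its
#' inputs; all outputs are new files under `out_dir`. The returned manifest
#' (also written to `manifest.json`) lists stages, settings, inputs and
#' outputs with content digests, and contains nothing time-dependent, so a
#' rerun with the same configuration yields an identical manifest.
#'
#' @param config See [run_config()].
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  config <- run_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)
  inputs <- character(0)
  note <- function(fmt, ...) message(sprintf(paste0("[indelcal] ", fmt), ...))

  if ("simulate" %in% config$stages) {
    t0 <- proc.time()[3]
    n_path <- config$n_path %||% 1000L
    n_benign <- config$n_benign %||% 1000L
    priors <- config$priors %||% list(deletion = 0.046, insertion = 0.008)
    rows <- list()
    for (vt in c("deletion", "insertion")) {
      tr <- synthetic_truth(
        score_dist_spec("gaussian", list(mean = 2, sd = 1)),
        score_dist_spec("gaussian", list(mean = 0, sd = 1)),
        prior = priors[[vt]],
        seed = config$seed + match(vt, c("deletion", "insertion")))
      ss <- gen_two_class_scores(tr, n_path, n_benign, tool = config$tool,
                                 variant_type = vt)
      rows[[vt]] <- data.frame(
        variant_id = sprintf("%s%06d", substr(vt, 1, 3),
                             seq_len(n_path + n_benign)),
        variant_type = vt,
        label = rep(c("pathogenic", "benign"), c(n_path, n_benign)),
        score = c(ss$pathogenic_scores, ss$benign_scores),
        stringsAsFactors = FALSE)
    }
    p <- pipeline_path(config, "scores.tsv")
    write_score_tsv(do.call(rbind, rows), p)
    outputs <- c(outputs, p)
    tp <- pipeline_path(config, "truth.json")
    jsonlite::write_json(list(model = "two-class gaussian",
                              pathogenic = list(mean = 2, sd = 1),
                              benign = list(mean = 0, sd = 1),
                              priors = priors, n_path = n_path,
                              n_benign = n_benign, seed = config$seed),
                         tp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    outputs <- c(outputs, tp)
    note("simulate: %d + %d scores per type (%.1fs)", n_path, n_benign,
         proc.time()[3] - t0)
  }

  if ("filter" %in% config$stages) {
    t0 <- proc.time()[3]
    vp <- config$variants %||% abort_config("filter stage needs `variants` input path")
    records <- read_variant_tsv(vp)
    inputs <- c(inputs, vp)
    res <- filter_clinical(records)
    kp <- pipeline_path(config, "variants_kept.tsv")
    write_variant_tsv(res$records, kp)
    ap <- pipeline_path(config, "filter_audit.json")
    write_audit_json(res$audit, ap)
    outputs <- c(outputs, kp, ap)
    note("filter: %d -> %d records (%.1fs)", nrow(records),
         res$audit$final_kept, proc.time()[3] - t0)
  }

  if ("prior" %in% config$stages) {
    t0 <- proc.time()[3]
    fp <- config$features_pos %||% abort_config("prior stage needs `features_pos`")
    fu <- config$features_unl %||% abort_config("prior stage needs `features_unl`")
    pos <- utils::read.delim(fp); unl <- utils::read.delim(fu)
    inputs <- c(inputs, fp, fu)
    pos_st <- pos$stratum; unl_st <- unl$stratum
    pos$stratum <- NULL; unl$stratum <- NULL
    est <- estimate_priors_stratified(as.matrix(pos), as.matrix(unl),
                                      pos_strata = pos_st, unl_strata = unl_st,
                                      n_reps = config$n_reps %||% 100L,
                                      seed = config$seed)
    pp <- pipeline_path(config, "prior_estimates.json")
    jsonlite::write_json(lapply(est, unclass), pp, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    outputs <- c(outputs, pp)
    note("prior: %s (%.1fs)",
         paste(sprintf("%s=%.3f", names(est),
                       vapply(est, `[[`, numeric(1), "alpha_hat")),
               collapse = ", "), proc.time()[3] - t0)
  }

  if ("calibrate" %in% config$stages) {
    t0 <- proc.time()[3]
    sp <- config$scores %||% pipeline_path(config, "scores.tsv")
    d <- read_score_tsv(sp)
    if (!"label" %in% names(d)) abort_input("calibration scores need a `label` column")
    if (!is.null(config$scores)) inputs <- c(inputs, sp)
    priors <- config$priors %||% abort_config("calibrate stage needs `priors`")
    rule <- window_rule(config$min_count, config$grid_size)
    thr_rows <- list()
    for (vt in intersect(c("deletion", "insertion"), unique(d$variant_type))) {
      dd <- d[d$variant_type == vt, ]
      set <- score_set(dd$score[dd$label == "pathogenic"],
                       dd$score[dd$label == "benign"],
                       tool = config$tool, variant_type = vt,
                       direction = config$direction)
      curve <- bootstrap_bounds(set, priors[[vt]], rule,
                                B = config$bootstrap_B, seed = config$seed)
      thr <- extract_thresholds(curve, point_scale(priors[[vt]]),
                                min_support = config$min_support)
      cp <- pipeline_path(config, sprintf("curve_%s.tsv", vt))
      write_curve_tsv(curve, cp)
      tp <- pipeline_path(config, sprintf("thresholds_%s.tsv", vt))
      write_thresholds_tsv(thr, tp)
      outputs <- c(outputs, cp, tp)
    }
    pv <- pipeline_path(config, "calibration_provenance.json")
    jsonlite::write_json(list(priors = priors, B = config$bootstrap_B,
                              seed = config$seed,
                              window = list(min_count = config$min_count %||% "adaptive",
                                            grid_size = config$grid_size),
                              min_support = config$min_support,
                              direction = config$direction, tool = config$tool),
                         pv, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    outputs <- c(outputs, pv)
    note("calibrate: done (%.1fs)", proc.time()[3] - t0)
  }

  if ("evaluate" %in% config$stages) {
    t0 <- proc.time()[3]
    tsp <- config$test_scores %||% pipeline_path(config, "scores.tsv")
    d <- read_score_tsv(tsp)
    inputs <- c(inputs, tsp)
    summary_out <- list()
    assign_rows <- list()
    for (vt in intersect(c("deletion", "insertion"), unique(d$variant_type))) {
      thp <- config$thresholds %||% pipeline_path(config, sprintf("thresholds_%s.tsv", vt))
      if (!file.exists(thp)) next
      thr <- read_thresholds_tsv(thp)
      if (!inherits(thr, "evidence_thresholds"))
        thr <- Filter(function(x) x$variant_type == vt, thr)[[1]]
      dd <- d[d$variant_type == vt, ]
      asg <- assign_points(dd$score, thr)
      asg$variant_id <- dd$variant_id
      assign_rows[[vt]] <- asg[, c("variant_id", "tool", "variant_type",
                                   "level", "score")]
      vt_summary <- list(bin_percent = as.list(bin_percentages(dd$score, thr)$percent))
      if ("label" %in% names(dd) && length(unique(dd$label)) == 2L) {
        lrs <- bin_likelihood_ratios(dd$score, dd$label, thr)
        lrs <- compare_to_expected(lrs, point_scale(thr$prior))
        vt_summary$bin_lrs <- lrs
      }
      if ("proband_id" %in% names(dd))
        vt_summary$proband_summary <- proband_evidence_summary(dd, thr)
      summary_out[[vt]] <- vt_summary
    }
    if (length(assign_rows)) {
      ap <- pipeline_path(config, "assignments.tsv")
      utils::write.table(do.call(rbind, assign_rows), ap, sep = "\t",
                         quote = FALSE, row.names = FALSE)
      outputs <- c(outputs, ap)
    }
    sp2 <- pipeline_path(config, "evaluation_summary.json")
    jsonlite::write_json(summary_out, sp2, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, force = TRUE)
    outputs <- c(outputs, sp2)
    note("evaluate: done (%.1fs)", proc.time()[3] - t0)
  }

  settings <- unclass(config)
  manifest <- list(
    stages = config$stages,
    settings = settings[setdiff(names(settings), "stages")],
    inputs = lapply(stats::setNames(nm = unique(inputs)), function(f)
      unname(tools::md5sum(f))),
    outputs = lapply(stats::setNames(nm = unique(outputs)), function(f)
      unname(tools::md5sum(f))))
  jsonlite::write_json(manifest, pipeline_path(config, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
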
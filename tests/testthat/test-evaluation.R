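test_that("evidence assignment follows the published interval conventions", {
  del <- published_by_tool("deletion")
  # boundary belongs to the stronger level throughout
  expect_identical(assign_points(22.5, del[["CADD"]])$level, 1L)
  expect_identical(assign_points(0.982, del[["FATHMM-indel"]])$level, 2L)
  expect_identical(assign_points(0.9819, del[["FATHMM-indel"]])$level, 1L)
  expect_identical(assign_points(0.40, del[["MutPred-Indel"]])$level, 0L)
  # inverted tools: more negative is stronger pathogenic
  expect_identical(assign_points(-23.07, del[["PROVEAN"]])$level, 3L)
  expect_identical(assign_points(-2.29, del[["PROVEAN"]])$level, -2L)
  expect_identical(assign_points(-0.28, del[["PROVEAN"]])$level, -4L)
  # missing scores propagate as missing assignments
  expect_true(is.na(assign_points(NA_real_, del[["CADD"]])$level))

  ins <- published_by_tool("insertion")
  expect_identical(assign_points(34.0, ins[["CADD"]])$level, 2L)
  expect_identical(assign_points(1.0, ins[["VEST-Indel"]])$level, 3L)
})

test_that("boundary audit: every finite interval end lands on its stated side", {
  for (vt in c("deletion", "insertion")) {
    for (thr in published_thresholds(vt)) {
      tab <- thr$levels
      for (i in seq_len(nrow(tab))) {
        lo <- tab$interval_low[i]; hi <- tab$interval_high[i]
        if (is.finite(lo)) {
          got <- assign_points(lo, thr)$level
          if (tab$low_inclusive[i]) expect_identical(got, tab$level[i])
          else expect_false(identical(got, tab$level[i]))
        }
        if (is.finite(hi)) {
          got <- assign_points(hi, thr)$level
          if (tab$high_inclusive[i]) expect_identical(got, tab$level[i])
          else expect_false(identical(got, tab$level[i]))
        }
        # an interior point always maps to its own level
        if (is.finite(lo) && is.finite(hi) && hi > lo)
          expect_identical(assign_points((lo + hi) / 2, thr)$level, tab$level[i])
      }
    }
  }
})

test_that("bin percentages partition scored variants and sum to 100", {
  thr <- published_by_tool("deletion")[["MutPred-Indel"]]
  set.seed(55)
  scores <- c(runif(400), rep(NA_real_, 100))
  bp <- bin_percentages(scores, thr)
  expect_equal(sum(bp$percent), 100, tolerance = 1e-9)
  expect_equal(bp$unscored_fraction, 0.2)
  expect_identical(bp$n_scored, 400L)

  # all scores in one bin
  bp1 <- bin_percentages(rep(0.9, 10), thr)
  expect_equal(unname(bp1$percent["+3"]), 100)

  # empty attained thresholds: everything is indeterminate
  empty <- toy_thresholds(data.frame(level = integer(), interval_low = numeric(),
                                     interval_high = numeric(),
                                     low_inclusive = logical(),
                                     high_inclusive = logical()))
  bp0 <- bin_percentages(runif(50), empty)
  expect_equal(unname(bp0$percent["0"]), 100)

  expect_error(bin_percentages(numeric(0), thr), class = "indelcal_input_error")

  # uniform scores: bin mass matches interval width within binomial noise
  thr_u <- toy_thresholds(data.frame(
    level = c(-1L, 1L), interval_low = c(-Inf, 0.8), interval_high = c(0.2, Inf),
    low_inclusive = c(FALSE, TRUE), high_inclusive = c(TRUE, FALSE)))
  set.seed(66)
  bpu <- bin_percentages(runif(20000), thr_u)
  expect_lt(abs(bpu$percent[["+1"]] - 20), 3 * 100 * sqrt(0.2 * 0.8 / 20000))
  expect_lt(abs(bpu$percent[["0"]] - 60), 3 * 100 * sqrt(0.6 * 0.4 / 20000))
})

test_that("bin likelihood ratios follow the counting definition", {
  thr_u <- toy_thresholds(data.frame(
    level = c(-1L, 1L), interval_low = c(-Inf, 0.8), interval_high = c(0.2, Inf),
    low_inclusive = c(FALSE, TRUE), high_inclusive = c(TRUE, FALSE)))
  # 10/100 pathogenic vs 2/200 benign in the +1 bin -> LR 10
  scores <- c(rep(0.9, 10), rep(0.5, 90), rep(0.9, 2), rep(0.5, 198))
  labels <- rep(c("pathogenic", "benign"), c(100, 200))
  lr <- bin_likelihood_ratios(scores, labels, thr_u)
  expect_equal(lr$lr[lr$level == 1], 10.0)
  expect_identical(lr$n_path_in_bin[lr$level == 1], 10L)

  # scale invariance: multiplying all counts by a constant leaves LRs fixed
  lr3 <- bin_likelihood_ratios(rep(scores, 3), rep(labels, 3), thr_u)
  expect_equal(lr3$lr, lr$lr)

  # zero false positives -> infinite; empty bin -> undefined (distinct)
  scores2 <- c(rep(0.9, 5), rep(0.5, 95), rep(0.5, 200))
  lr2 <- bin_likelihood_ratios(scores2, labels, thr_u)
  expect_identical(lr2$lr[lr2$level == 1], Inf)
  expect_true(lr2$defined[lr2$level == 1])
  expect_true(is.nan(lr2$lr[lr2$level == -1]))
  expect_false(lr2$defined[lr2$level == -1])

  # proportional capture in a bin gives LR 1 on both sides
  scores3 <- c(rep(0.1, 50), rep(0.5, 50), rep(0.1, 100), rep(0.5, 100))
  lr4 <- bin_likelihood_ratios(scores3, labels, thr_u)
  expect_equal(lr4$lr[lr4$level == -1], 1.0)  # inverse of 1 is 1

  expect_error(bin_likelihood_ratios(rep(0.5, 5), rep("pathogenic", 5), thr_u),
               "benign")
})

test_that("expected-minimum comparison passes and fails at the framework bounds", {
  scale <- point_scale(0.046)
  mk <- function(level, lr) data.frame(level = level, n_path_in_bin = 1L,
                                       n_benign_in_bin = 1L, n_path_total = 10L,
                                       n_benign_total = 10L, lr = lr,
                                       reported_as = if (level > 0) "standard" else "inverse",
                                       defined = !is.nan(lr))
  res <- compare_to_expected(rbind(mk(1, 3.0), mk(2, 5.0), mk(1, Inf),
                                   mk(-1, 3.0), mk(2, NaN)), scale)
  expect_identical(res$pass, c(TRUE, FALSE, TRUE, TRUE, NA))
  expect_equal(round(res$expected_lr[1], 2), 2.39)
  expect_equal(round(res$expected_lr[2], 2), 5.71)
})

test_that("length stratification partitions in-frame indels exactly", {
  expect_identical(stratify_by_length(c(-3L, 9L, 3L, -12L)),
                   c("single_aa", "multi_aa", "single_aa", "multi_aa"))
  expect_error(stratify_by_length(c(3L, 4L)), class = "indelcal_input_error")
  expect_error(stratify_by_length(0L), class = "indelcal_input_error")

  # per-stratum bin counts recombine to the whole-set counts
  thr_u <- toy_thresholds(data.frame(
    level = c(-1L, 1L), interval_low = c(-Inf, 0.8), interval_high = c(0.2, Inf),
    low_inclusive = c(FALSE, TRUE), high_inclusive = c(TRUE, FALSE)))
  set.seed(77)
  scores <- runif(300); labels <- rep(c("pathogenic", "benign"), 150)
  net <- sample(c(-3L, 3L, 6L, -9L), 300, TRUE)
  strat <- stratify_by_length(net)
  whole <- bin_likelihood_ratios(scores, labels, thr_u)
  parts <- lapply(c("single_aa", "multi_aa"), function(sa) {
    sel <- strat == sa
    bin_likelihood_ratios(scores[sel], labels[sel], thr_u)
  })
  expect_identical(whole$n_path_in_bin,
                   parts[[1]]$n_path_in_bin + parts[[2]]$n_path_in_bin)
  expect_identical(whole$n_benign_in_bin,
                   parts[[1]]$n_benign_in_bin + parts[[2]]$n_benign_in_bin)
})

test_that("proband summaries reproduce planted counts exactly", {
  thr <- published_by_tool("deletion")[["MutPred-Indel"]]
  co <- gen_proband_cohort(10, list("0" = 2, "+1" = 1), thr, seed = 5)
  ps <- proband_evidence_summary(co$scores, thr, probands = co$planted$proband_id)
  expect_equal(ps$mean[ps$level == 1], 1.0)
  expect_equal(ps$mean[ps$level == 0], 2.0)
  expect_identical(unname(unlist(ps[ps$level == 1, c("min", "max")])),
                   c(1L, 1L))

  # hand arithmetic: two probands with level-0 counts {2, 4}
  co2 <- data.frame(proband_id = c("a", "a", "b", "b", "b", "b"),
                    score = rep(0.4, 6))  # 0.4 is indeterminate for MutPred
  ps2 <- proband_evidence_summary(co2, thr)
  expect_equal(ps2$mean[ps2$level == 0], 3.0)
  expect_identical(ps2$min[ps2$level == 0], 2L)
  expect_identical(ps2$max[ps2$level == 0], 4L)

  # probands with no variants contribute zeros at every level
  ps3 <- proband_evidence_summary(co2, thr, probands = c("a", "b", "c", "d"))
  expect_equal(ps3$mean[ps3$level == 0], 1.5)
  expect_identical(ps3$min[ps3$level == 0], 0L)

  expect_error(proband_evidence_summary(data.frame(proband_id = character(),
                                                   score = numeric()), thr),
               class = "indelcal_input_error")
})

test_that("thresholds survive a TSV round trip with identical assignments", {
  tr <- gaussian_truth(prior = 0.046, seed = 56)
  ss <- gen_two_class_scores(tr, 1500, 1500, seed = 56)
  cv <- bootstrap_bounds(ss, 0.046, B = 150, seed = 57)
  thr <- extract_thresholds(cv, point_scale(0.046), 10)
  path <- tempfile(fileext = ".tsv")
  on.exit(unlink(path))
  write_thresholds_tsv(thr, path)
  thr2 <- read_thresholds_tsv(path)
  set.seed(58)
  probe <- runif(10000, min(cv$grid) - 1, max(cv$grid) + 1)
  expect_identical(assign_points(probe, thr)$level,
                   assign_points(probe, thr2)$level)
})
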
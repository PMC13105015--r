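test_that("score orientation is an involution and flips only inverted tools", {
  hp <- score_set(c(2, 3), c(0, 1), direction = "higher_pathogenic")
  expect_identical(orient_scores(hp)$pathogenic_scores, c(2, 3))

  lp <- score_set(c(-23.07, -10), c(1, 2), direction = "lower_pathogenic")
  o <- orient_scores(lp)
  expect_identical(o$pathogenic_scores, c(23.07, 10))
  expect_true(o$oriented)
  back <- orient_scores(o)
  expect_identical(back$pathogenic_scores, lp$pathogenic_scores)
})

test_that("local posterior matches the window-count formula by hand", {
  # windows holding only pathogenic points give posterior 1
  set <- score_set(rep(10, 50), rep(0, 50))
  lp <- local_posterior_at(10, set, 0.046, window_rule(min_count = 10, min_class = 0))
  expect_equal(lp$posterior, 1)

  # equal local class fractions return the prior
  set2 <- score_set(seq(0, 1, length.out = 100), seq(0, 1, length.out = 100))
  lp2 <- local_posterior_at(0.5, set2, 0.046, window_rule(min_count = 40, min_class = 0))
  expect_equal(lp2$posterior, 0.046, tolerance = 1e-9)

  # hand arithmetic: c_P/n_P = 30/100, c_B/n_B = 10/100, prior 0.046
  expect_equal(
    indelcal:::posterior_from_counts(30, 10, 100, 100, 0.046),
    0.0138 / 0.1092, tolerance = 1e-12)
  expect_equal(round(0.0138 / 0.1092, 3), 0.126)
})

test_that("posterior curve tracks the analytic oracle on Gaussian data", {
  tr <- gaussian_truth(prior = 0.046, seed = 1)
  ss <- gen_two_class_scores(tr, 3000, 3000, seed = 5)
  cv <- estimate_posterior_curve(ss, 0.046)
  expect_length(cv$estimate, 1001)
  expect_true(all(cv$estimate >= 0 & cv$estimate <= 1))
  # pooled window count satisfied except where the window saturates
  expect_true(all(cv$c_path + cv$c_benign >= cv$settings$min_count |
                    cv$half_width >= diff(range(cv$grid)) / 2))
  ap <- analytic_posterior(tr, cv$grid)
  rng <- c(max(quantile(ss$pathogenic_scores, 0.05),
               quantile(ss$benign_scores, 0.05)),
           min(quantile(ss$pathogenic_scores, 0.95),
               quantile(ss$benign_scores, 0.95)))
  sel <- cv$grid >= rng[1] & cv$grid <= rng[2]
  expect_lt(max(abs(cv$estimate - ap)[sel]), 0.05)

  # identical class samples estimate the prior everywhere
  same <- gen_two_class_scores(gaussian_truth(prior = 0.046, mu_path = 0, seed = 2),
                               5000, 5000, seed = 9)
  cvs <- estimate_posterior_curve(same, 0.046)
  expect_lt(max(abs(cvs$estimate - 0.046)), 0.02)
})

test_that("bootstrap bounds bracket the estimate and degenerate correctly", {
  tr <- gaussian_truth(prior = 0.1, seed = 3)
  ss <- gen_two_class_scores(tr, 500, 500, seed = 3)

  # B = 1: both bounds equal that single replicate's curve
  cv1 <- bootstrap_bounds(ss, 0.1, B = 1, seed = 4)
  expect_identical(cv1$lower, cv1$upper)

  # percentile property: lower bound rarely exceeds the point estimate
  cv <- bootstrap_bounds(ss, 0.1, B = 200, seed = 4)
  expect_true(all(cv$lower <= cv$upper))
  expect_gte(mean(cv$lower <= cv$estimate + 1e-12), 0.99)

  # fully separated degenerate composition: top of the curve pinned at 1
  sep <- score_set(rep(1, 120), rep(0, 120))
  cvs <- bootstrap_bounds(sep, 0.5, window_rule(min_count = 10, min_class = 0),
                          B = 20, seed = 1)
  expect_equal(cvs$lower[length(cvs$lower)], 1)

  expect_error(bootstrap_bounds(ss, 0.1, B = 10),
               class = "indelcal_config_error")  # missing seed

  # determinism: same seed, same curve and bounds
  cv2 <- bootstrap_bounds(ss, 0.1, B = 50, seed = 11)
  cv3 <- bootstrap_bounds(ss, 0.1, B = 50, seed = 11)
  expect_identical(cv2[c("estimate", "lower", "upper")],
                   cv3[c("estimate", "lower", "upper")])
})

test_that("threshold extraction reads a constructed step bound exactly", {
  # hand-built curve: lower bound steps over the +1 posterior bound exactly
  # at oriented grid score 1.30; upper bound never allows benign evidence
  scale <- point_scale(0.046)
  p1 <- posterior_threshold_for_level(0.046, 1)
  grid <- seq(0, 2, by = 0.01)
  lower <- ifelse(grid >= 1.30, p1 + 1e-9, p1 - 0.05)
  upper <- pmin(lower + 0.1, 1)
  set <- score_set(seq(1, 2, length.out = 60), seq(0, 1.2, length.out = 60))
  cv <- estimate_posterior_curve(set, 0.046,
                                 window_rule(min_count = 10, grid_size = length(grid),
                                             min_class = 0))
  cv$grid <- grid; cv$lower <- lower; cv$upper <- upper
  thr <- extract_thresholds(cv, scale, min_support = 1)
  expect_equal(thr$levels$threshold[thr$levels$level == 1], 1.30)
  # +2..+4 and all benign levels unreachable on this curve
  expect_identical(sort(thr$levels$level), 1L)
})

test_that("support exclusion drops extreme levels with a reason", {
  scale <- point_scale(0.046)
  p1 <- posterior_threshold_for_level(0.046, 1)
  p2 <- posterior_threshold_for_level(0.046, 2)
  grid <- seq(0, 2, by = 0.01)
  lower <- ifelse(grid >= 1.0, p1 + 1e-9, 0)
  lower[grid >= 1.9] <- p2 + 1e-9   # +2 attained only in the last sliver
  set <- score_set(seq(0.5, 1.85, length.out = 100), seq(0, 1, length.out = 100))
  cv <- estimate_posterior_curve(set, 0.046,
                                 window_rule(min_count = 10, grid_size = length(grid),
                                             min_class = 0))
  cv$grid <- grid; cv$lower <- lower; cv$upper <- rep(1, length(grid))
  thr <- extract_thresholds(cv, scale, min_support = 10)
  lev2 <- thr$levels[thr$levels$level == 2, ]
  expect_identical(lev2$excluded_reason, "insufficient extreme support")
  # the +1 interval then extends over the excluded region
  lev1 <- thr$levels[thr$levels$level == 1, ]
  expect_identical(lev1$interval_high, Inf)
})

test_that("stringent-bound thresholds are at least as extreme as point-estimate ones", {
  tr <- gaussian_truth(prior = 0.046, seed = 6)
  ss <- gen_two_class_scores(tr, 2000, 2000, seed = 6)
  cv <- bootstrap_bounds(ss, 0.046, B = 300, seed = 7)
  scale <- point_scale(0.046)
  thr_b <- extract_thresholds(cv, scale, min_support = 10)
  thr_p <- indelcal:::thresholds_from_bounds(cv, cv$estimate, cv$estimate,
                                             scale, 10)
  for (k in intersect(thr_b$levels$level, thr_p$levels$level)) {
    tb <- thr_b$levels$threshold[thr_b$levels$level == k]
    tp <- thr_p$levels$threshold[thr_p$levels$level == k]
    if (k > 0) expect_gte(tb, tp) else expect_lte(tb, tp)
  }
})

test_that("emitted intervals are disjoint, ordered, with boundaries to the stronger level", {
  tr <- gaussian_truth(prior = 0.046, seed = 16)
  ss <- gen_two_class_scores(tr, 2000, 2000, seed = 16)
  cv <- bootstrap_bounds(ss, 0.046, B = 300, seed = 17)
  thr <- extract_thresholds(cv, point_scale(0.046), min_support = 10)
  tab <- thr$levels[is.na(thr$levels$excluded_reason), ]
  tab <- tab[order(tab$interval_low), ]
  # disjoint and ordered on the raw axis
  expect_true(all(tab$interval_high[-nrow(tab)] <= tab$interval_low[-1] + 1e-12))
  # each finite threshold maps back to its own level; a nudge toward the
  # weaker side leaves it
  for (i in seq_len(nrow(tab))) {
    k <- tab$level[i]
    thr_score <- tab$threshold[i]
    expect_identical(assign_points(thr_score, thr)$level, k)
  }
})

test_that("lowering the prior never relaxes attained thresholds", {
  tr <- gaussian_truth(prior = 0.046, seed = 26)
  ss <- gen_two_class_scores(tr, 2000, 2000, seed = 26)
  priors <- c(0.2, 0.046, 0.008)
  thrs <- lapply(priors, function(a) {
    cv <- bootstrap_bounds(ss, a, B = 200, seed = 27)
    extract_thresholds(cv, point_scale(a), min_support = 10)
  })
  for (i in seq_len(length(priors) - 1)) {
    hi <- thrs[[i]]$levels; lo <- thrs[[i + 1]]$levels
    for (k in intersect(hi$level[is.na(hi$excluded_reason)],
                        lo$level[is.na(lo$excluded_reason)])) {
      t_hi <- hi$threshold[hi$level == k]
      t_lo <- lo$threshold[lo$level == k]
      if (k > 0) expect_gte(t_lo, t_hi - 1e-12)
      else expect_lte(t_lo, t_hi + 1e-12)
    }
  }
})

test_that("per-type calibration is independent and a lower prior is more extreme", {
  tr_del <- gaussian_truth(prior = 0.046, seed = 36)
  del <- gen_two_class_scores(tr_del, 2000, 2000, seed = 36,
                              variant_type = "deletion")
  ins <- gen_two_class_scores(tr_del, 2000, 2000, seed = 36,
                              variant_type = "insertion")
  res <- calibrate_tool(insertion_set = ins, deletion_set = del,
                        insertion_prior = 0.008, deletion_prior = 0.046,
                        B = 200, seed = 37)
  # identical scores, lower insertion prior: insertion thresholds at least
  # as extreme for every attained level
  di <- res$deletion$thresholds$levels
  ii <- res$insertion$thresholds$levels
  for (k in intersect(di$level[is.na(di$excluded_reason)],
                      ii$level[is.na(ii$excluded_reason)])) {
    td <- di$threshold[di$level == k]; ti <- ii$threshold[ii$level == k]
    if (k > 0) expect_gte(ti, td - 1e-12) else expect_lte(ti, td + 1e-12)
  }
  # per-type output equals a single-type run with the same settings
  expect_warning(
    single <- calibrate_tool(deletion_set = del, deletion_prior = 0.046,
                             B = 200, seed = 37),
    "insertion")
  expect_identical(single$deletion$thresholds$levels,
                   res$deletion$thresholds$levels)
})

test_that("thresholds for an inverted tool are reported in original units", {
  tr <- gaussian_truth(prior = 0.1, seed = 46)
  base <- gen_two_class_scores(tr, 1500, 1500, seed = 46)
  inv <- score_set(-base$pathogenic_scores, -base$benign_scores,
                   tool = "inv", direction = "lower_pathogenic")
  cv_b <- bootstrap_bounds(base, 0.1, B = 200, seed = 47)
  cv_i <- bootstrap_bounds(inv, 0.1, B = 200, seed = 47)
  thr_b <- extract_thresholds(cv_b, point_scale(0.1), 10)
  thr_i <- extract_thresholds(cv_i, point_scale(0.1), 10)
  tb <- thr_b$levels[is.na(thr_b$levels$excluded_reason), ]
  ti <- thr_i$levels[is.na(thr_i$levels$excluded_reason), ]
  expect_setequal(tb$level, ti$level)
  for (k in tb$level) {
    # mirrored interval: [lo, hi) of the upright tool becomes (-hi, -lo]
    rb <- tb[tb$level == k, ]; ri <- ti[ti$level == k, ]
    expect_equal(ri$interval_low, -rb$interval_high)
    expect_equal(ri$interval_high, -rb$interval_low)
    expect_identical(ri$low_inclusive, rb$high_inclusive)
  }
})
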
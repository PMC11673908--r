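# cohort statistics: U, S/r/AUC identities, ROC, thresholds, correlations

test_that("mann_whitney handles separation and ties as expected", {
  ms <- mann_whitney(1:3, 4:6)
  expect_equal(ms$U, 0)
  expect_equal(separation(ms$U, 3, 3)$auc, 1)   # oriented classifier

  mt <- mann_whitney(c(5, 5, 5), c(5, 5, 5))
  sep <- separation(mt$U, 3, 3)
  expect_equal(sep$S, 0.5)
  expect_equal(sep$auc, 0.5)
  expect_equal(mt$p, 1)
})

test_that("U equals the brute-force pairwise count on 200 random tied instances", {
  set.seed(20)
  for (rep in 1:200) {
    n1 <- sample(2:15, 1); n2 <- sample(2:15, 1)
    x <- sample(1:8, n1, replace = TRUE)   # heavy ties
    y <- sample(1:8, n2, replace = TRUE)
    expect_equal(mann_whitney(x, y)$U, brute_u(x, y))
  }
})

test_that("normal-approximation p agrees with the reference implementation", {
  set.seed(31)
  for (rep in 1:25) {
    x <- rnorm(sample(10:40, 1)); y <- rnorm(sample(10:40, 1), 0.4)
    got <- mann_whitney(x, y)
    ref <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                               correct = TRUE))
    expect_equal(got$U, unname(ref$statistic))
    expect_equal(got$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("the exact permutation p matches the approximation for small clean samples", {
  set.seed(5)
  x <- rnorm(6); y <- rnorm(6, 1)
  pe <- mann_whitney(x, y, method = "exact")$p
  ref <- stats::wilcox.test(x, y, exact = TRUE)$p.value
  expect_equal(pe, ref, tolerance = 1e-12)
})

test_that("separation reproduces the printed AUC-effect size pairs", {
  n1 <- 56; n2 <- 70
  # AUC 0.987 printed for the forefoot distance AB classifier
  sep_ab <- separation((1 - 0.987) * n1 * n2, n1, n2)
  expect_equal(round(sep_ab$r, 3), 0.974)
  # AUC 0.838 printed for the ap position of marker D
  sep_apd <- separation((1 - 0.838) * n1 * n2, n1, n2)
  expect_equal(round(sep_apd$r, 3), 0.676)
  expect_error(separation(n1 * n2 + 1, n1, n2), "out of range")
})

test_that("effect sizes are labeled by the r thresholds", {
  expect_identical(effect_label(0.974), "large")
  expect_identical(effect_label(0.38), "large")
  expect_identical(effect_label(0.37), "medium")
  expect_identical(effect_label(0.353), "medium")
  expect_identical(effect_label(0.3), "small")
  expect_identical(effect_label(0.096), "very small")
  expect_error(effect_label(1.2), "\\[0, 1\\]")
})

test_that("ROC sweep has proper endpoints and both AUC routes agree", {
  roc <- roc_curve(c(3, 4, 5), c(0, 1, 2))
  expect_equal(roc$auc_u, 1)
  expect_true(any(roc$fpr == 0 & roc$tpr == 1))   # passes through (0, 1)
  expect_equal(min(roc$tpr), 0); expect_equal(max(roc$fpr), 1)

  set.seed(40)
  for (rep in 1:100) {
    a <- rnorm(sample(5:30, 1)); b <- rnorm(sample(5:30, 1), runif(1, 0, 2))
    r <- roc_curve(a, b)
    expect_equal(r$auc_trapezoid, r$auc_u, tolerance = 1e-9)
  }
  big <- roc_curve(rnorm(1000), rnorm(1000))
  expect_lt(abs(big$auc_u - 0.5), 0.03)
  expect_error(roc_curve(rep(1, 5), rep(1, 5)), "degenerate")
})

test_that("optimal threshold maximizes sqrt(TPR*TNR) and hits gap midpoints", {
  r <- roc_curve(c(3, 4), c(1, 2))
  opt <- optimal_threshold(r)
  expect_equal(opt$G, 1)
  expect_equal(opt$threshold, 2.5)

  r1 <- roc_curve(0, 1)          # single value per cohort
  o1 <- optimal_threshold(r1)
  expect_equal(o1$threshold, 0.5)
  expect_equal(o1$G, 1)

  set.seed(50)
  for (rep in 1:100) {
    a <- round(rnorm(sample(4:25, 1)), 1)
    b <- round(rnorm(sample(4:25, 1), runif(1, 0, 1.5)), 1)
    if (length(unique(c(a, b))) < 2) next
    roc <- roc_curve(a, b)
    opt <- optimal_threshold(roc)
    expect_equal(opt$G, brute_best_g(a, b, roc$orientation),
                 tolerance = 1e-12)
    # reported G dominates every other swept threshold
    g_all <- sqrt(roc$tpr * (1 - roc$fpr))
    expect_gte(opt$G + 1e-12, max(g_all[is.finite(roc$thresholds)]))
  }
})

test_that("negating all scores leaves AUC, G and confusion unchanged", {
  set.seed(60)
  a <- rnorm(30, 1); b <- rnorm(40)
  r1 <- roc_curve(a, b); r2 <- roc_curve(-a, -b)
  expect_false(r1$orientation == r2$orientation)
  expect_equal(r1$auc_u, r2$auc_u, tolerance = 1e-12)
  o1 <- optimal_threshold(r1); o2 <- optimal_threshold(r2)
  expect_equal(o1$G, o2$G, tolerance = 1e-12)
  c1 <- confusion_percent(a, b, o1$threshold, r1$orientation)
  c2 <- confusion_percent(-a, -b, o2$threshold, r2$orientation)
  expect_equal(c1$tp_pct, c2$tp_pct, tolerance = 1e-12)
  expect_equal(c1$fp_pct, c2$fp_pct, tolerance = 1e-12)
})

test_that("confusion percentages are exact fractions of the cohort sizes", {
  pos <- c(rep(1, 55), -1)       # 1 of 56 below the threshold
  neg <- c(rep(-1, 68), 1, 1)    # 2 of 70 above
  cf <- confusion_percent(pos, neg, 0, "high")
  expect_equal(round(cf$fn_pct, 2), 1.79)
  expect_equal(round(cf$fp_pct, 2), 2.86)
  expect_equal(cf$tp_pct + cf$fn_pct, 100)
  expect_equal(cf$tn_pct + cf$fp_pct, 100)

  all_pos <- confusion_percent(c(1, 2), c(3, 4), -10, "high")
  expect_equal(all_pos$tp_pct, 100)
  expect_equal(all_pos$fp_pct, 100)
})

test_that("compare_cohorts applies the large-effect rule for thresholds", {
  set.seed(70)
  base <- as.data.frame(matrix(rnorm(20 * 15), 20, 15))
  names(base) <- parameter_names()
  base$BI <- abs(base$BI) + 0.5

  # copied cohorts: everything is a random classifier, no thresholds at all
  cmp_same <- suppressWarnings(compare_cohorts(base, base,
                                               calibrate_bi = FALSE))
  expect_true(all(cmp_same$auc == 0.5))
  expect_true(all(is.na(cmp_same$threshold)))

  # plant a strong effect on AB only; the other rows stay blank
  shifted <- base
  shifted$AB <- shifted$AB + 6
  cmp <- compare_cohorts(shifted, base, calibrate_bi = FALSE)
  ab <- cmp[cmp$parameter == "AB", ]
  expect_identical(ab$effect, "large")
  expect_false(is.na(ab$threshold))
  weak <- cmp[cmp$parameter == "AE", ]   # same distribution -> small effect
  expect_lte(weak$r, 0.37)
  expect_true(is.na(weak$threshold))
  expect_equal(cmp$auc, (1 + cmp$r) / 2, tolerance = 1e-12)
})

test_that("non-finite parameter values give an all-NA row with a warning", {
  set.seed(71)
  a <- as.data.frame(matrix(rnorm(10 * 15), 10, 15))
  names(a) <- parameter_names()
  b <- a + 1
  b$Ra[3] <- Inf
  expect_warning(cmp <- compare_cohorts(b, a, calibrate_bi = FALSE),
                 "non-finite")
  expect_true(is.na(cmp$auc[cmp$parameter == "Ra"]))
})

test_that("BI-parameter correlations match the closed-form OLS oracle", {
  set.seed(80)
  bi <- exp(rnorm(60, 3, 0.5))
  ab <- 0.03 + 0.02 * log10(bi) + rnorm(60, 0, 0.01)
  got <- correlate_with_bi(ab, bi, transform_x = "log10",
                           transform_y = "identity")
  ora <- brute_ols(log10(bi), ab)
  expect_equal(got$slope, ora$slope, tolerance = 1e-10)
  expect_equal(got$intercept, ora$intercept, tolerance = 1e-10)
  expect_equal(got$r_squared, ora$r_squared, tolerance = 1e-10)

  # exact line -> R^2 = 1
  x <- 1:10
  perfect <- suppressWarnings(            # lm warns on an exact fit
    correlate_with_bi(2 * x + 1, x, transform_x = "identity",
                      transform_y = "identity"))
  expect_equal(perfect$r_squared, 1, tolerance = 1e-12)

  expect_error(correlate_with_bi(rep(1, 10), x, transform_x = "identity"),
               "zero variance")
  expect_error(correlate_with_bi(1:5, c(-1, 2, 3, 4, 5)), "positive")
})
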
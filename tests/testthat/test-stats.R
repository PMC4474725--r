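sync_bp <- read_performance_csv(benchmark_table_path("synchronous", "bp"))
selfp_bp <- read_performance_csv(benchmark_table_path("selfpaced", "bp"))

test_that("mean-tie ranks reproduce the published average ranks", {
  rk <- rank_table(selfp_bp)
  expect_equal(unname(rk$average_ranks["LR"]), 1.8125)
  expect_equal(truncate_decimals(unname(rk$average_ranks["LR"]), 2), 1.81)
  expect_equal(unname(rk$average_ranks["MLP"]), 2.75)
  expect_equal(truncate_decimals(unname(rk$average_ranks["LDA"]), 2), 3.06)
  expect_equal(truncate_decimals(unname(rk$average_ranks["RF"]), 2), 4.87)
  # rank sums per subject are k(k+1)/2 whatever the ties
  expect_equal(unname(rowSums(rk$ranks)), rep(28, 8))
})

test_that("tied scores receive mean ranks and preserve the rank-sum identity", {
  scores <- rbind(c(2, 2, 1), c(3, 3, 3), c(1, 2, 3))
  rk <- rank_table(performance_table(scores))
  expect_equal(unname(rk$ranks[1, ]), c(1.5, 1.5, 3))
  expect_equal(unname(rk$ranks[2, ]), c(2, 2, 2))
  expect_equal(unname(rowSums(rk$ranks)), rep(6, 3))
})

test_that("the Friedman statistic matches theory and base R", {
  # all-equal performance: chi2 = 0, p = 1
  rk0 <- rank_table(performance_table(matrix(1, 5, 4)))
  fr0 <- friedman_rank_test(rk0)
  expect_equal(fr0$chi2, 0)
  expect_equal(fr0$p_value, 1)
  expect_equal(fr0$df, 3L)
  # tie-free random tables: statistic equals stats::friedman.test exactly
  set.seed(30)
  for (i in 1:20) {
    scores <- matrix(rnorm(8 * 5), 8, 5)
    ours <- friedman_rank_test(rank_table(performance_table(scores)))
    ref <- stats::friedman.test(scores)
    expect_equal(ours$chi2, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("k = 2 Friedman agrees with the exhaustive sign-flip distribution", {
  set.seed(31)
  scores <- matrix(rnorm(6 * 2), 6, 2)
  rk <- rank_table(performance_table(scores))
  chi2 <- friedman_rank_test(rk)$chi2
  # enumerate all 2^6 orderings under the null to get the exact law of chi2
  signs <- as.matrix(expand.grid(rep(list(c(1, 2)), 6)))
  null_chi2 <- apply(signs, 1, function(r1) {
    ranks <- cbind(r1, 3 - r1)
    R <- colMeans(ranks)
    12 * 6 / (2 * 3) * (sum(R^2) - 2 * 9 / 4)
  })
  exact_p <- mean(null_chi2 >= chi2 - 1e-12)
  asym_p <- friedman_rank_test(rk)$p_value
  # observed statistic must be a realizable value of the exact distribution
  expect_true(any(abs(null_chi2 - chi2) < 1e-9))
  # chi-square approximation tracks the exact tail at moderate p
  expect_lt(abs(asym_p - exact_p), 0.12)
})

test_that("Friedman is invariant to subject-wise monotone transforms", {
  set.seed(32)
  scores <- matrix(runif(10 * 4), 10, 4)
  f1 <- friedman_rank_test(rank_table(performance_table(scores)))
  warped <- t(apply(scores, 1, function(r) exp(3 * r) + 1))
  f2 <- friedman_rank_test(rank_table(performance_table(warped)))
  expect_equal(f1$chi2, f2$chi2, tolerance = 1e-12)
})

test_that("Holm comparisons reproduce the published p-values (self-paced, BP)", {
  holm <- holm_posthoc(rank_table(selfp_bp), alpha = 0.1)
  expect_equal(holm$control, "LR")
  p <- setNames(truncate_decimals(holm$comparisons$p_value, 4),
                holm$comparisons$classifier)
  expect_equal(unname(p["SVM"]), 0.0002)
  expect_equal(unname(p["BST"]), 0.0006)
  expect_equal(unname(p["RF"]), 0.0045)
  expect_equal(unname(p["QDA"]), 0.0278)
  expect_equal(unname(p["LDA"]), 0.2471)
  expect_equal(unname(p["MLP"]), 0.3854)
  # k - 1 comparisons, control excluded, ascending p, stepped thresholds
  expect_equal(nrow(holm$comparisons), 6L)
  expect_false("LR" %in% holm$comparisons$classifier)
  expect_true(!is.unsorted(holm$comparisons$p_value))
  expect_equal(holm$comparisons$threshold, 0.1 / (6:1))
})

test_that("Holm comparisons reproduce the published p-values (synchronous, BP)", {
  holm <- holm_posthoc(rank_table(sync_bp), alpha = 0.1)
  expect_equal(holm$control, "MLP")
  p <- setNames(truncate_decimals(holm$comparisons$p_value, 4),
                holm$comparisons$classifier)
  expect_equal(unname(p["RF"]), 0.0006)
  expect_equal(unname(p["QDA"]), 0.0010)
  expect_equal(unname(p["BST"]), 0.0151)
  expect_equal(unname(p["LDA"]), 0.0801)
  expect_equal(unname(p["SVM"]), 0.7750)
  expect_equal(unname(p["LR"]), 0.9430)
})

test_that("Holm p-values do not depend on non-control column order", {
  perm <- c(1, 7, 3, 5, 2, 6, 4)
  shuffled <- performance_table(selfp_bp$scores[, perm])
  h1 <- holm_posthoc(rank_table(selfp_bp), 0.1)
  h2 <- holm_posthoc(rank_table(shuffled), 0.1)
  expect_equal(h2$comparisons$p_value, h1$comparisons$p_value,
               tolerance = 1e-12)
  expect_equal(h2$comparisons$classifier, h1$comparisons$classifier)
})

test_that("recommended sets follow the step-down rejections", {
  rec_sync <- recommended_set(holm_posthoc(rank_table(sync_bp), 0.1))
  expect_setequal(rec_sync$recommended, c("MLP", "LR", "SVM", "LDA"))
  expect_setequal(rec_sync$not_recommended, c("BST", "QDA", "RF"))

  # strong separation: everything rejected -> only the control remains
  set.seed(33)
  strong <- matrix(rep(c(10, 1, 1, 1, 1), each = 30), 30, 5) +
    matrix(runif(150, 0, 0.1), 30, 5)
  hs <- holm_posthoc(rank_table(performance_table(strong)), 0.1)
  expect_equal(recommended_set(hs)$recommended, hs$control)

  # pure noise at tiny alpha: nothing rejected -> everyone recommended
  noise <- matrix(runif(150), 30, 5)
  hn <- holm_posthoc(rank_table(performance_table(noise)), 1e-6)
  expect_length(recommended_set(hn)$recommended, 5L)
})

test_that("degenerate statistics inputs are refused", {
  expect_error(performance_table(matrix(1, 1, 3)), ">= 2 subjects")
  expect_error(performance_table(matrix(1, 3, 1)), ">= 2 classifiers")
  expect_error(performance_table(matrix(c(1, NA, 2, 3), 2, 2)), "missing")
})

test_that("comparison reports serialize to JSON with full structure", {
  cmp <- compare_classifiers(selfp_bp, alpha = 0.1)
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  write_comparison_json(cmp, path)
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(js$control, "LR")
  expect_setequal(js$recommended, c("LR", "LDA", "MLP"))
  expect_equal(js$friedman$df, 6L)
  expect_equal(nrow(js$holm), 6L)
})
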
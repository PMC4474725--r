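pipe_lda <- function(seg = NULL)
  bci_pipeline("bp", time_segment = seg, n_csp_pairs = 1,
               classifier = classifier_spec("LDA"))

test_that("cross-validation is stratified, seeded and reproducible", {
  ep <- small_synth_epochs(trials_per_class = 10, seed = 25)
  cv1 <- crossval_score(pipe_lda(), ep, n_repeats = 2, n_folds = 5, seed = 3)
  cv2 <- crossval_score(pipe_lda(), ep, n_repeats = 2, n_folds = 5, seed = 3)
  expect_identical(cv1, cv2)
  expect_equal(nrow(cv1$folds), 10L)
  folds <- bcibench:::stratified_folds(ep$labels, 5, seed = 3)
  for (k in 1:5)
    expect_equal(as.integer(table(ep$labels[folds == k])), c(2L, 2L))
})

test_that("cross-validation recovers strong ERD and stays at chance without it", {
  # strongly separable regime: deep ERD, low sensor noise
  ep <- small_synth_epochs(trials_per_class = 15, seed = 26, erd = 0.2,
                           noise_sd = 2)
  cv <- crossval_score(pipe_lda(), ep, n_repeats = 1, n_folds = 5, seed = 1)
  expect_gte(cv$mean, 0.9)
  ep0 <- small_synth_epochs(trials_per_class = 10, seed = 27, erd = 1)
  cv0 <- crossval_score(pipe_lda(), ep0, n_repeats = 1, n_folds = 5, seed = 1)
  expect_gte(cv0$mean, 0.25)
  expect_lte(cv0$mean, 0.75)   # wide band: only 100 validation trials total
})

test_that("too few trials per class for the fold count errors out", {
  ep <- small_synth_epochs(trials_per_class = 3, seed = 28)
  expect_error(crossval_score(pipe_lda(), ep, n_folds = 5), "fewer trials")
})

test_that("grid search returns the single config and breaks ties deterministically", {
  ep <- small_synth_epochs(trials_per_class = 8, seed = 29)
  sp1 <- search_space(feature_family = "bp", time_segments = list(c(0, 2)),
                      csp_pairs = 1,
                      classifier_grids = list(LDA = default_grid("LDA")))
  gs1 <- grid_search(sp1, ep, n_repeats = 1, n_folds = 4, seed = 2)
  expect_equal(gs1$best_config$time_segment, c(0, 2))
  expect_equal(gs1$best_config$kind, "LDA")
  # duplicated candidate axes give identical scores; the first wins
  sp2 <- search_space(feature_family = "bp",
                      time_segments = list(c(0, 2), c(0, 2)),
                      csp_pairs = 1,
                      classifier_grids = list(LDA = default_grid("LDA")))
  gs2 <- grid_search(sp2, ep, n_repeats = 1, n_folds = 4, seed = 2)
  expect_equal(gs2$config_means$mean[1], gs2$config_means$mean[2])
  expect_equal(gs2$best_mean, gs1$best_mean)
  expect_error(grid_search(search_space(time_segments = list()), ep), "candidate")
})

test_that("grid search prefers the time segment where the ERD lives", {
  # trials are 2 s of modulation preceded by an unmodulated 2 s gap, so a
  # (-1, 2) epoch contains discriminative signal only in [0, 2]: the
  # tighter candidate segment must win
  sc <- synth_config(trials_per_class = 12, trial_length_s = 2,
                     inter_trial_gap_s = 2, noise_sd = 5, seed = 30)
  rec <- generate_synchronous(sc)
  ep <- extract_epochs(rec, -1, 2,
                       label_map = c(left = "left", right = "right"))
  sp <- search_space(feature_family = "bp",
                     time_segments = list(c(-1, 2), c(0, 2)),
                     csp_pairs = 1,
                     classifier_grids = list(LDA = default_grid("LDA")))
  gs <- grid_search(sp, ep, n_repeats = 2, n_folds = 4, seed = 4)
  expect_equal(gs$best_config$time_segment, c(0, 2))
})

test_that("adding a configuration never lowers the best score", {
  ep <- small_synth_epochs(trials_per_class = 8, seed = 31)
  small <- search_space(feature_family = "bp", time_segments = list(c(0, 2)),
                        csp_pairs = 1,
                        classifier_grids = list(LDA = default_grid("LDA")))
  bigger <- search_space(feature_family = "bp",
                         time_segments = list(c(0, 2), c(0.5, 1.5)),
                         csp_pairs = 1,
                         classifier_grids = list(LDA = default_grid("LDA")))
  g1 <- grid_search(small, ep, n_repeats = 1, n_folds = 4, seed = 5)
  g2 <- grid_search(bigger, ep, n_repeats = 1, n_folds = 4, seed = 5)
  expect_gte(g2$best_mean, g1$best_mean)
})

test_that("final fit refuses leakage and ignores test-label corruption", {
  tr <- small_synth_epochs(trials_per_class = 8, seed = 32)
  te <- small_synth_epochs(trials_per_class = 6, seed = 33)
  cfg <- list(feature_family = "bp", time_segment = NULL, n_csp_pairs = 1,
              window_config = NULL, kind = "LDA", hyperparameters = list(),
              bands = list(c(8, 12), c(16, 24)), morlet = morlet_spec(),
              morlet_prefilter = c(4, 30), seed = 1)
  expect_error(fit_final_and_test(cfg, tr, tr), "leakage")
  res <- fit_final_and_test(cfg, tr, te, metric = "accuracy")
  expect_gte(res$score, 0.85)
  # corrupting test labels changes the score but not the trained model's
  # predictions on unchanged inputs
  te_bad <- te
  te_bad$labels <- rev(te$labels)
  res_bad <- fit_final_and_test(cfg, tr, te_bad, metric = "accuracy")
  expect_identical(res_bad$predictions$probabilities,
                   res$predictions$probabilities)
})

test_that("self-paced search evaluates window configurations", {
  spc <- selfpaced_config(synth_config(trials_per_class = 1, seed = 34),
                          total_length_s = 90)
  gen <- generate_selfpaced(spc)
  data <- list(recording = gen$recording,
               control_intervals = gen$control_intervals)
  sp <- search_space(feature_family = "bp", csp_pairs = 1,
                     window_configs = list(sliding_window_config(1, 0.5),
                                           sliding_window_config(2, 0.5)),
                     classifier_grids = list(LDA = default_grid("LDA")))
  gs <- grid_search(sp, data, n_repeats = 1, n_folds = 4, seed = 6,
                    metric = "auc")
  expect_s3_class(gs$best_config$window_config, "bci_window_config")
  expect_true(gs$best_mean > 0.5)
  spc2 <- selfpaced_config(synth_config(trials_per_class = 1, seed = 35),
                           total_length_s = 90)
  gen2 <- generate_selfpaced(spc2)
  res <- fit_final_and_test(gs$best_config,
                            data,
                            list(recording = gen2$recording,
                                 control_intervals = gen2$control_intervals),
                            metric = "auc")
  expect_gt(res$score, 0.5)
})
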
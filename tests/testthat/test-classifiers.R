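test_that("default grids expose the tuned-parameter schema per learner", {
  expect_length(default_grid("LDA")$axes, 0)
  expect_length(default_grid("QDA")$axes, 0)
  expect_named(default_grid("SVM_RBF")$axes, c("cost", "gamma_scale"))
  expect_named(default_grid("LR")$axes, c("alpha", "lambda"))
  expect_named(default_grid("RF")$axes,
               c("n_trees", "max_features", "max_depth", "min_leaf"))
  expect_named(default_grid("ADABOOST")$axes,
               c("n_trees", "max_features", "max_depth", "learning_rate"))
  expect_named(default_grid("MLP")$axes,
               c("hidden_units", "l1", "l2", "learning_rate"))
  expect_error(default_grid("KNN"), "arg")
  expect_error(classifier_spec("LR", list(bogus = 1)), "unknown hyperparameters")
  # empty grid enumerates exactly one (default) configuration
  expect_length(grid_configs(default_grid("LDA")), 1)
  expect_length(grid_configs(default_grid("SVM_RBF")), 12)
})

test_that("all seven classifiers separate Gaussian blobs and emit valid probabilities", {
  fm <- blob_features(n_per_class = 100, sep = 6, seed = 1)
  for (kind in classifier_kinds()) {
    model <- train_classifier(classifier_spec(kind, seed = 7), fm)
    pred <- predict_proba(model, fm)
    expect_equal(rowSums(pred$probabilities), rep(1, 200), tolerance = 1e-6,
                 info = kind)
    expect_true(all(pred$probabilities >= 0 & pred$probabilities <= 1),
                info = kind)
    expect_gte(accuracy(predicted_labels(pred), fm$labels), 0.99)
  }
})

test_that("RBF-SVM handles XOR where LDA cannot", {
  fm <- xor_features(n = 400, seed = 2)
  tr <- feature_matrix(fm$values[1:300, ], fm$feature_names, fm$labels[1:300])
  te <- feature_matrix(fm$values[301:400, ], fm$feature_names, fm$labels[301:400])
  svm_acc <- accuracy(predicted_labels(predict_proba(
    train_classifier(classifier_spec("SVM_RBF"), tr), te)), te$labels)
  lda_acc <- accuracy(predicted_labels(predict_proba(
    train_classifier(classifier_spec("LDA"), tr), te)), te$labels)
  expect_gte(svm_acc, 0.9)
  expect_lte(lda_acc, 0.6)
})

test_that("stochastic learners are reproducible given spec and seed", {
  fm <- blob_features(n_per_class = 40, sep = 3, seed = 3)
  for (kind in c("RF", "ADABOOST", "MLP", "SVM_RBF")) {
    p1 <- predict_proba(train_classifier(classifier_spec(kind, seed = 42), fm), fm)
    p2 <- predict_proba(train_classifier(classifier_spec(kind, seed = 42), fm), fm)
    expect_identical(p1$probabilities, p2$probabilities, info = kind)
  }
})

test_that("class renaming permutes probability columns identically", {
  fm <- blob_features(n_per_class = 50, sep = 4, seed = 4)
  fm2 <- fm
  fm2$labels <- ifelse(fm$labels == "a", "zeta", "alpha")  # reverses sort order
  # deterministic learners: exact equivariance; the random forest consumes
  # its RNG stream in a level-order-dependent way, so only approximate
  for (kind in c("LDA", "LR", "RF")) {
    tol <- if (kind == "RF") 0.05 else 1e-6
    p1 <- predict_proba(train_classifier(classifier_spec(kind, seed = 1), fm), fm)
    p2 <- predict_proba(train_classifier(classifier_spec(kind, seed = 1), fm2), fm2)
    expect_equal(p1$class_order, c("a", "b"))
    expect_equal(p2$class_order, c("alpha", "zeta"))
    # "a" -> "zeta" (column 2), "b" -> "alpha" (column 1)
    expect_equal(p2$probabilities[, c(2, 1)], p1$probabilities,
                 tolerance = tol, info = kind)
  }
})

test_that("softmax of all-zero scores is uniform over K classes", {
  for (K in c(2, 4, 7)) {
    P <- bcibench:::softmax_rows(matrix(0, 3, K))
    expect_equal(P, matrix(1 / K, 3, K))
  }
})

test_that("SVM probability ranking follows the decision margin", {
  fm <- blob_features(n_per_class = 60, sep = 2.5, seed = 5)
  model <- train_classifier(classifier_spec("SVM_RBF", seed = 1), fm)
  pred <- predict_proba(model, fm)
  X <- sweep(sweep(fm$values, 2, model$scaler$mean), 2, model$scaler$sd, "/")
  dv <- attr(predict(model$fit, X, decision.values = TRUE), "decision.values")[, 1]
  # Platt scaling is monotone in the decision value, so the rank orderings
  # agree up to the orientation of the binary decision axis
  rho <- cor(rank(pred$probabilities[, 1]), rank(dv), method = "spearman")
  expect_equal(abs(rho), 1, tolerance = 1e-10)
})

test_that("degenerate training inputs are refused", {
  fm <- blob_features(n_per_class = 20, seed = 6)
  one <- feature_matrix(fm$values[1:20, ], fm$feature_names, fm$labels[1:20])
  expect_error(train_classifier(classifier_spec("LDA"), one), "single class")
  model <- train_classifier(classifier_spec("LDA"), fm)
  expect_error(predict_proba(model, fm$values[, 1, drop = FALSE]), "mismatch")
})

test_that("QDA survives singular per-class covariances via shrinkage", {
  set.seed(9)
  # 30 samples, 40 correlated features: per-class covariance is singular
  X <- matrix(rnorm(30 * 40), 30, 40)
  fm <- feature_matrix(X, sprintf("f%02d", 1:40), rep(c("a", "b"), 15))
  model <- train_classifier(classifier_spec("QDA"), fm)
  pred <- predict_proba(model, fm)
  expect_equal(rowSums(pred$probabilities), rep(1, 30), tolerance = 1e-6)
})
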
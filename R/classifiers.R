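#' Classifier specification
#'
#' Uniform description of one of the seven benchmarked classifiers:
#' Gaussian discriminant analysis with shared (`LDA`) or free (`QDA`)
#' covariances, elastic-net logistic regression (`LR`), RBF-kernel support
#' vector machine (`SVM_RBF`), random forest (`RF`), AdaBoost over shallow
#' trees (`ADABOOST`), and a single-hidden-layer perceptron (`MLP`).
#'
#' @param kind one of `"LDA"`, `"QDA"`, `"LR"`, `"SVM_RBF"`, `"RF"`,
#'   `"ADABOOST"`, `"MLP"`.
#' @param hyperparameters named list; names must belong to the kind's grid
#'   schema (see [default_grid()]).
#' @param seed integer seed for stochastic learners.
#' @return object of class `bci_classifier_spec`.
#' @export
classifier_spec <- function(kind, hyperparameters = list(), seed = 1L) {
  kind <- match.arg(kind, classifier_kinds())
  allowed <- grid_schema(kind)
  bad <- setdiff(names(hyperparameters), allowed)
  if (length(bad))
    stop("unknown hyperparameters for ", kind, ": ",
         paste(bad, collapse = ", "))
  structure(list(kind = kind, hyperparameters = hyperparameters,
                 seed = as.integer(seed)),
            class = "bci_classifier_spec")
}

#' @rdname classifier_spec
#' @export
classifier_kinds <- function() {
  c("LDA", "QDA", "LR", "SVM_RBF", "RF", "ADABOOST", "MLP")
}

grid_schema <- function(kind) {
  switch(kind,
    LDA = character(0),
    QDA = character(0),
    LR = c("alpha", "lambda"),
    SVM_RBF = c("cost", "gamma_scale"),
    RF = c("n_trees", "max_features", "max_depth", "min_leaf"),
    ADABOOST = c("n_trees", "max_features", "max_depth", "learning_rate"),
    MLP = c("hidden_units", "l1", "l2", "learning_rate"),
    stop("unknown classifier kind: ", kind))
}

#' Default hyperparameter grid per classifier kind
#'
#' Grid axes follow the tuned-parameter schema of each learner: none for
#' the Gaussian discriminant classifiers; regularization type (elastic-net
#' mixing `alpha`) and coefficient (`lambda`) for LR; `cost` and RBF width
#' for the SVM (`gamma_scale` multiplies the `1/n_features` heuristic);
#' tree count, feature-subset size, depth and leaf size for RF; tree count,
#' feature-subset size, depth and learning rate for AdaBoost; hidden-layer
#' width, L1/L2 coefficients and learning rate for the MLP. The candidate
#' values themselves are package configuration defaults and fully
#' overridable.
#'
#' @param kind a classifier kind, see [classifier_spec()].
#' @return object of class `bci_param_grid` with an `axes` list (empty for
#'   LDA/QDA).
#' @export
default_grid <- function(kind) {
  kind <- match.arg(kind, classifier_kinds())
  axes <- switch(kind,
    LDA = list(),
    QDA = list(),
    LR = list(alpha = c(0, 0.5, 1), lambda = c(1e-4, 1e-3, 1e-2, 1e-1)),
    SVM_RBF = list(cost = c(0.1, 1, 10, 100), gamma_scale = c(0.1, 1, 10)),
    RF = list(n_trees = c(100, 300), max_features = c(0.33, 1),
              max_depth = c(3, 10), min_leaf = c(1, 5)),
    ADABOOST = list(n_trees = c(50, 100), max_features = c(1),
                    max_depth = c(1, 3), learning_rate = c(0.5, 1)),
    MLP = list(hidden_units = c(5, 20), l1 = c(0, 1e-4), l2 = c(0, 1e-3),
               learning_rate = c(0.05, 0.2)))
  param_grid(kind, axes)
}

#' @rdname default_grid
#' @param axes named list of candidate-value vectors; names must belong to
#'   the kind's schema.
#' @export
param_grid <- function(kind, axes) {
  kind <- match.arg(kind, classifier_kinds())
  allowed <- grid_schema(kind)
  bad <- setdiff(names(axes), allowed)
  if (length(bad))
    stop("unknown grid axes for ", kind, ": ", paste(bad, collapse = ", "))
  if (length(axes) && any(!vapply(axes, length, 1L)))
    stop("grid axes must be non-empty")
  structure(list(kind = kind, axes = axes), class = "bci_param_grid")
}

#' Enumerate all hyperparameter combinations of a grid
#' @param grid a [param_grid()].
#' @return list of hyperparameter lists (a single empty list for an empty
#'   grid).
#' @export
grid_configs <- function(grid) {
  stopifnot(inherits(grid, "bci_param_grid"))
  if (!length(grid$axes)) return(list(list()))
  df <- expand.grid(grid$axes, KEEP.OUT.ATTRS = FALSE)
  lapply(seq_len(nrow(df)), function(i) as.list(df[i, , drop = FALSE]))
}

# run code under a seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

feature_values <- function(features) {
  if (inherits(features, "bci_features")) features$values
  else as.matrix(features)
}

check_trainable <- function(X, y) {
  if (!all(is.finite(X))) stop("non-finite feature values")
  tab <- table(y)
  if (length(tab) < 2L) stop("training data contains a single class")
  if (any(tab < 2L))
    stop("class '", names(tab)[which.min(tab)], "' has fewer than 2 samples")
}

#' Train a classifier under the uniform contract
#'
#' Fits the learner named by `spec` to a labeled feature matrix. Training
#' is deterministic given `(spec, seed, features)`. Scale-sensitive
#' learners (SVM, LR, MLP) standardize features internally using training
#' statistics that are frozen into the model, so prediction never touches
#' test-set statistics; tree ensembles are left unscaled.
#'
#' @param spec a [classifier_spec()].
#' @param features a [feature_matrix()] with >= 2 classes, each with >= 2
#'   samples.
#' @return object of class `bci_model` exposing [predict_proba()].
#' @export
train_classifier <- function(spec, features) {
  stopifnot(inherits(spec, "bci_classifier_spec"))
  X <- feature_values(features)
  y <- factor(features$labels, levels = sort(unique(features$labels)))
  check_trainable(X, y)
  scaled <- spec$kind %in% c("SVM_RBF", "LR", "MLP")
  scaler <- NULL
  if (scaled) {
    mu <- colMeans(X)
    sd <- apply(X, 2, stats::sd)
    sd[sd < 1e-12] <- 1
    scaler <- list(mean = mu, sd = sd)
    X <- sweep(sweep(X, 2, mu), 2, sd, "/")
  }
  hp <- spec$hyperparameters
  fit <- with_seed(spec$seed, switch(spec$kind,
    LDA = MASS::lda(X, grouping = y),
    QDA = fit_qda_safe(X, y),
    LR = fit_glmnet(X, y, hp),
    SVM_RBF = fit_svm(X, y, hp),
    RF = fit_rf(X, y, hp),
    ADABOOST = fit_adaboost(X, y, hp, spec$seed),
    MLP = fit_mlp(X, y, hp, spec$seed)))
  structure(list(kind = spec$kind, spec = spec, fit = fit, scaler = scaler,
                 levels = levels(y), n_features = ncol(X),
                 feature_names = colnames(X)),
            class = "bci_model")
}

#' @export
print.bci_model <- function(x, ...) {
  cat(sprintf("<bci_model> %s, %d features, classes: %s\n",
              x$kind, x$n_features, paste(x$levels, collapse = ", ")))
  invisible(x)
}

#' Class-probability predictions
#'
#' @param model a [train_classifier()] result.
#' @param features a [feature_matrix()] or plain matrix with the same
#'   feature count used in training.
#' @return object of class `bci_prediction`: a list with `probabilities`
#'   (samples x classes, rows summing to one) and `class_order` (sorted
#'   class labels).
#' @export
predict_proba <- function(model, features) {
  stopifnot(inherits(model, "bci_model"))
  X <- feature_values(features)
  if (ncol(X) != model$n_features)
    stop("feature count mismatch: model expects ", model$n_features,
         ", got ", ncol(X))
  if (!is.null(model$scaler))
    X <- sweep(sweep(X, 2, model$scaler$mean), 2, model$scaler$sd, "/")
  P <- switch(model$kind,
    LDA = predict(model$fit, X)$posterior,
    QDA = predict_qda_safe(model$fit, X),
    LR = predict_glmnet(model$fit, X),
    SVM_RBF = predict_svm(model$fit, X),
    RF = predict(model$fit, X, type = "prob"),
    ADABOOST = predict_adaboost(model$fit, X),
    MLP = predict_mlp(model$fit, X))
  P <- as.matrix(P)[, model$levels, drop = FALSE]
  P[P < 0] <- 0
  P <- P / rowSums(P)
  structure(list(probabilities = unname(P), class_order = model$levels),
            class = "bci_prediction")
}

#' Hard labels from a probability prediction
#'
#' Argmax over class probabilities; exact ties go to the earliest label in
#' sorted order, keeping predictions deterministic.
#'
#' @param pred a [predict_proba()] result.
#' @return character vector of predicted labels.
#' @export
predicted_labels <- function(pred) {
  stopifnot(inherits(pred, "bci_prediction"))
  pred$class_order[apply(pred$probabilities, 1, which.max)]
}

## ---- per-kind fitting backends ------------------------------------------

fit_qda_safe <- function(X, y) {
  out <- tryCatch(list(kind = "mass", fit = MASS::qda(X, grouping = y)),
                  error = function(e) NULL)
  if (!is.null(out)) return(out)
  # shrinkage fallback for singular per-class covariances: fit Gaussians
  # with a 1e-6 * I ridge
  classes <- levels(y)
  d <- ncol(X)
  fits <- lapply(classes, function(cl) {
    Xi <- X[y == cl, , drop = FALSE]
    S <- stats::cov(Xi) + diag(1e-6, d)
    ch <- chol(S)
    list(mean = colMeans(Xi), chol = ch,
         logdet = 2 * sum(log(diag(ch))), prior = nrow(Xi) / nrow(X))
  })
  names(fits) <- classes
  list(kind = "ridge", fits = fits, classes = classes)
}

predict_qda_safe <- function(fit, X) {
  if (fit$kind == "mass") return(predict(fit$fit, X)$posterior)
  ll <- sapply(fit$fits, function(f) {
    D <- sweep(X, 2, f$mean)
    Z <- backsolve(f$chol, t(D), transpose = TRUE)
    -0.5 * colSums(Z^2) - 0.5 * f$logdet + log(f$prior)
  })
  if (is.null(dim(ll))) ll <- matrix(ll, nrow = 1,
                                     dimnames = list(NULL, fit$classes))
  P <- softmax_rows(ll)
  colnames(P) <- fit$classes
  P
}

fit_glmnet <- function(X, y, hp) {
  alpha <- hp$alpha %||% 0.5
  lambda <- hp$lambda %||% 1e-3
  path <- sort(unique(c(10^seq(1, -6, length.out = 40), lambda)),
               decreasing = TRUE)
  fit <- glmnet::glmnet(X, y, family = "multinomial", alpha = alpha,
                        lambda = path, standardize = FALSE)
  list(fit = fit, lambda = lambda, classes = levels(y))
}

predict_glmnet <- function(m, X) {
  P <- predict(m$fit, newx = X, s = m$lambda, type = "response")
  P <- P[, , 1, drop = FALSE]
  dim(P) <- dim(P)[1:2]
  colnames(P) <- m$classes
  P
}

fit_svm <- function(X, y, hp) {
  cost <- hp$cost %||% 1
  gamma <- (hp$gamma_scale %||% 1) / ncol(X)
  e1071::svm(X, y, kernel = "radial", cost = cost, gamma = gamma,
             probability = TRUE)
}

predict_svm <- function(fit, X) {
  pr <- predict(fit, X, probability = TRUE)
  attr(pr, "probabilities")
}

fit_rf <- function(X, y, hp) {
  d <- ncol(X)
  mtry <- max(1L, min(d, round((hp$max_features %||% 0.33) * d)))
  maxnodes <- if (is.null(hp$max_depth)) NULL
              else max(2L, min(2L^hp$max_depth, nrow(X)))
  randomForest::randomForest(X, y, ntree = hp$n_trees %||% 300,
                             mtry = mtry, maxnodes = maxnodes,
                             nodesize = hp$min_leaf %||% 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## AdaBoost (SAMME) over rpart weak learners. The multiclass weight update
## uses the log(K-1) offset so boosting remains valid for K > 2; the
## learning rate shrinks each stage's vote.
fit_adaboost <- function(X, y, hp, seed) {
  M <- hp$n_trees %||% 50
  depth <- hp$max_depth %||% 1
  lr <- hp$learning_rate %||% 1
  frac <- hp$max_features %||% 1
  K <- nlevels(y)
  n <- nrow(X)
  d <- ncol(X)
  nfeat <- max(1L, round(frac * d))
  w <- rep(1 / n, n)
  stages <- list()
  df <- data.frame(X)
  ctrl <- rpart::rpart.control(maxdepth = depth, minsplit = 2,
                               minbucket = 1, cp = 0, xval = 0)
  for (m in seq_len(M)) {
    feats <- if (nfeat < d) sort(sample.int(d, nfeat)) else seq_len(d)
    dat <- df[, feats, drop = FALSE]
    dat$.y <- y
    tree <- rpart::rpart(.y ~ ., data = dat, weights = w, method = "class",
                         control = ctrl)
    pred <- predict(tree, dat, type = "class")
    wrong <- as.numeric(pred != y)
    err <- sum(w * wrong)
    err <- min(max(err, 1e-10), 1 - 1e-10)
    if (err >= (1 - 1 / K)) {
      if (!length(stages)) {
        stages[[1]] <- list(tree = tree, feats = feats, alpha = 1e-10)
      }
      break
    }
    alpha <- lr * (log((1 - err) / err) + log(K - 1))
    stages[[length(stages) + 1L]] <- list(tree = tree, feats = feats,
                                          alpha = alpha)
    w <- w * exp(alpha * wrong)
    w <- w / sum(w)
  }
  list(stages = stages, classes = levels(y))
}

predict_adaboost <- function(fit, X) {
  K <- length(fit$classes)
  scores <- matrix(0, nrow(X), K, dimnames = list(NULL, fit$classes))
  df <- data.frame(X)
  for (s in fit$stages) {
    dat <- df[, s$feats, drop = FALSE]
    pred <- predict(s$tree, dat, type = "class")
    scores[cbind(seq_len(nrow(X)), as.integer(pred))] <-
      scores[cbind(seq_len(nrow(X)), as.integer(pred))] + s$alpha
  }
  tot <- sum(vapply(fit$stages, `[[`, numeric(1), "alpha"))
  P <- scores / tot
  # guard rows with zero mass (cannot happen with >= 1 stage, kept defensive)
  P[rowSums(P) == 0, ] <- 1 / K
  P
}

## Single-hidden-layer perceptron: tanh hidden units, softmax output,
## negative log-likelihood plus L1 and L2 penalties, full-batch gradient
## descent with early stopping on a 10 % validation split. All randomness
## (initialization, split) is derived from the classifier seed.
fit_mlp <- function(X, y, hp, seed, epochs = 300L, patience = 25L) {
  H <- hp$hidden_units %||% 10
  l1 <- hp$l1 %||% 0
  l2 <- hp$l2 %||% 1e-4
  lr <- hp$learning_rate %||% 0.1
  n <- nrow(X); d <- ncol(X); K <- nlevels(y)
  Y <- diag(K)[as.integer(y), , drop = FALSE]
  n_val <- max(2L, floor(0.1 * n))
  val_idx <- sample.int(n, n_val)
  tr_idx <- setdiff(seq_len(n), val_idx)
  W1 <- matrix(stats::runif(d * H, -0.5, 0.5) / sqrt(d), d, H)
  b1 <- rep(0, H)
  W2 <- matrix(stats::runif(H * K, -0.5, 0.5) / sqrt(H), H, K)
  b2 <- rep(0, K)
  fwd <- function(X) {
    A <- tanh(sweep(X %*% W1, 2, b1, "+"))
    P <- softmax_rows(sweep(A %*% W2, 2, b2, "+"))
    list(A = A, P = P)
  }
  nll <- function(idx) {
    P <- fwd(X[idx, , drop = FALSE])$P
    -mean(log(pmax(rowSums(P * Y[idx, , drop = FALSE]), 1e-12)))
  }
  best <- list(W1 = W1, b1 = b1, W2 = W2, b2 = b2, val = Inf)
  stall <- 0L
  Xtr <- X[tr_idx, , drop = FALSE]
  Ytr <- Y[tr_idx, , drop = FALSE]
  m <- length(tr_idx)
  for (ep in seq_len(epochs)) {
    f <- fwd(Xtr)
    G2 <- (f$P - Ytr) / m                         # d NLL / d logits
    gW2 <- crossprod(f$A, G2) + l2 * 2 * W2 + l1 * sign(W2)
    gb2 <- colSums(G2)
    GA <- (G2 %*% t(W2)) * (1 - f$A^2)
    gW1 <- crossprod(Xtr, GA) + l2 * 2 * W1 + l1 * sign(W1)
    gb1 <- colSums(GA)
    W2 <- W2 - lr * gW2; b2 <- b2 - lr * gb2
    W1 <- W1 - lr * gW1; b1 <- b1 - lr * gb1
    v <- nll(val_idx)
    if (v < best$val - 1e-9) {
      best <- list(W1 = W1, b1 = b1, W2 = W2, b2 = b2, val = v)
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= patience) break
    }
  }
  c(best[c("W1", "b1", "W2", "b2")], list(classes = levels(y)))
}

predict_mlp <- function(fit, X) {
  A <- tanh(sweep(X %*% fit$W1, 2, fit$b1, "+"))
  P <- softmax_rows(sweep(A %*% fit$W2, 2, fit$b2, "+"))
  colnames(P) <- fit$classes
  P
}
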
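#' End-to-end BCI pipeline configuration
#'
#' Binds the three processing stages into one trainable unit: frequency
#' filtering (filter bank for the band-power family, a broad pre-filter for
#' the Morlet family), optional CSP spatial filtering, feature extraction,
#' and a classifier. All supervised stages (CSP, feature scaling, the
#' classifier) are fit on training data only and frozen for prediction.
#'
#' @param feature_family `"bp"` (filter-bank band power + log) or
#'   `"morlet"` (wavelet band power).
#' @param bands filter-bank bands for the BP family; defaults to the alpha
#'   (8-12 Hz) and beta (16-24 Hz) rhythms.
#' @param time_segment optional `c(start_s, end_s)` crop relative to the
#'   cue, applied before any fitting (synchronous paradigm).
#' @param n_csp_pairs number of CSP filter pairs per band, or `NULL` to
#'   skip spatial filtering (e.g. low-channel montages).
#' @param morlet a [morlet_spec()] (Morlet family only).
#' @param morlet_prefilter broad band-pass applied before wavelet
#'   decomposition.
#' @param classifier a [classifier_spec()].
#' @param filter_order Butterworth order for all filtering.
#' @return object of class `bci_pipeline`.
#' @export
bci_pipeline <- function(feature_family = c("bp", "morlet"),
                         bands = list(c(8, 12), c(16, 24)),
                         time_segment = NULL,
                         n_csp_pairs = NULL,
                         morlet = morlet_spec(),
                         morlet_prefilter = c(4, 30),
                         classifier = classifier_spec("LDA"),
                         filter_order = 5L) {
  feature_family <- match.arg(feature_family)
  structure(list(feature_family = feature_family, bands = bands,
                 time_segment = time_segment, n_csp_pairs = n_csp_pairs,
                 morlet = morlet, morlet_prefilter = morlet_prefilter,
                 classifier = classifier, filter_order = filter_order),
            class = "bci_pipeline")
}

# fit CSP for one band: plain two-class CSP for binary problems,
# one-against-others concatenation for multiclass
fit_band_csp <- function(ep, n_pairs) {
  classes <- sort(unique(ep$labels))
  if (length(classes) == 2L) {
    f <- fit_csp(class_covariance(ep, classes[1]),
                 class_covariance(ep, classes[2]),
                 class_pair = classes)
    list(select_filters(f, n_pairs))
  } else {
    lapply(fit_csp_ovr(ep), select_filters, n_pairs = n_pairs)
  }
}

project_band <- function(filter_sets, ep) {
  pieces <- lapply(filter_sets, apply_csp, ep = ep)
  out <- pieces[[1]]
  if (length(pieces) > 1L) {
    out$epochs <- do.call(abind_channels, lapply(pieces, `[[`, "epochs"))
    out$channel_labels <- unlist(lapply(seq_along(pieces), function(i)
      sprintf("csp_%s_%02d", names(filter_sets)[i] %||% i,
              seq_len(dim(pieces[[i]]$epochs)[2]))))
  }
  out
}

abind_channels <- function(...) {
  arrs <- list(...)
  d <- dim(arrs[[1]])
  total <- sum(vapply(arrs, function(a) dim(a)[2], 1L))
  out <- array(0, dim = c(d[1], total, d[3]))
  at <- 0L
  for (a in arrs) {
    k <- dim(a)[2]
    out[, (at + 1L):(at + k), ] <- a
    at <- at + k
  }
  out
}

pipeline_transform <- function(state, ep) {
  pipe <- state$pipe
  if (!is.null(pipe$time_segment))
    ep <- crop_epochs(ep, pipe$time_segment[1], pipe$time_segment[2])
  ep <- center_epochs(ep)
  if (pipe$feature_family == "bp") {
    bank <- filter_bank(pipe$bands, pipe$filter_order)
    bands <- apply_filterbank(ep, bank)
    if (!is.null(state$csp)) {
      bands <- lapply(names(bands), function(bn)
        project_band(state$csp[[bn]], bands[[bn]]))
      names(bands) <- names(state$csp)
    }
    bp_features(bands)
  } else {
    bank <- filter_bank(list(pipe$morlet_prefilter), pipe$filter_order)
    broad <- apply_filterbank(ep, bank)[[1]]
    if (!is.null(state$csp))
      broad <- project_band(state$csp[[1]], broad)
    morlet_features(broad, pipe$morlet)
  }
}

#' Fit a pipeline on training epochs
#'
#' @param pipe a [bci_pipeline()].
#' @param ep training [epoch_set()] (cued trials, or labeled windows for
#'   the self-paced paradigm).
#' @return object of class `bci_fitted_pipeline`.
#' @export
fit_pipeline <- function(pipe, ep) {
  stopifnot(inherits(pipe, "bci_pipeline"), inherits(ep, "bci_epochs"))
  state <- list(pipe = pipe, csp = NULL)
  if (!is.null(pipe$n_csp_pairs)) {
    prep <- ep
    if (!is.null(pipe$time_segment))
      prep <- crop_epochs(prep, pipe$time_segment[1], pipe$time_segment[2])
    prep <- center_epochs(prep)
    if (pipe$feature_family == "bp") {
      bank <- filter_bank(pipe$bands, pipe$filter_order)
      bands <- apply_filterbank(prep, bank)
      state$csp <- lapply(bands, fit_band_csp, n_pairs = pipe$n_csp_pairs)
    } else {
      bank <- filter_bank(list(pipe$morlet_prefilter), pipe$filter_order)
      broad <- apply_filterbank(prep, bank)[[1]]
      state$csp <- list(fit_band_csp(broad, pipe$n_csp_pairs))
    }
  }
  fm <- pipeline_transform(state, ep)
  model <- train_classifier(pipe$classifier, fm)
  structure(list(state = state, model = model,
                 train_ids = ep$trial_ids,
                 classes = sort(unique(ep$labels))),
            class = "bci_fitted_pipeline")
}

#' Predict class probabilities from a fitted pipeline
#'
#' @param fitted a [fit_pipeline()] result.
#' @param ep epochs to score.
#' @return a [predict_proba()] prediction.
#' @export
predict_pipeline <- function(fitted, ep) {
  stopifnot(inherits(fitted, "bci_fitted_pipeline"))
  fm <- pipeline_transform(fitted$state, ep)
  predict_proba(fitted$model, fm)
}

score_metric <- function(pred, labels, metric, positive = "control") {
  if (metric == "accuracy") {
    accuracy(predicted_labels(pred), labels)
  } else {
    col <- match(positive, pred$class_order)
    if (is.na(col)) stop("positive class '", positive, "' absent from model")
    auc_score(pred$probabilities[, col], labels, positive)
  }
}

stratified_folds <- function(labels, n_folds, seed) {
  folds <- integer(length(labels))
  with_seed(seed, {
    for (cl in sort(unique(labels))) {
      idx <- which(labels == cl)
      idx <- sample(idx)
      folds[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  folds
}

#' Repeated stratified cross-validation of a pipeline
#'
#' Performs `n_repeats` runs of stratified `n_folds`-fold cross-validation
#' (5 x 5 by default). Every supervised stage -- CSP, feature scaling, the
#' classifier -- is refit inside each training fold, so no information
#' leaks from validation folds. Fold assignments for repeat `r` are drawn
#' from the derived seed `seed + r`, making the whole procedure
#' reproducible.
#'
#' @param pipe a [bci_pipeline()].
#' @param ep labeled epochs; every class needs at least `n_folds` trials.
#' @param n_repeats,n_folds repetition and fold counts.
#' @param seed integer seed.
#' @param metric `"accuracy"` (synchronous) or `"auc"` (self-paced
#'   windows).
#' @return list with `mean` and a `folds` data.frame (`rep`, `fold`,
#'   `score`).
#' @export
crossval_score <- function(pipe, ep, n_repeats = 5L, n_folds = 5L, seed = 1L,
                           metric = c("accuracy", "auc")) {
  metric <- match.arg(metric)
  tab <- table(ep$labels)
  if (any(tab < n_folds))
    stop("class '", names(tab)[which.min(tab)], "' has fewer trials (",
         min(tab), ") than folds (", n_folds, ")")
  rows <- list()
  for (r in seq_len(n_repeats)) {
    folds <- stratified_folds(ep$labels, n_folds, seed + r)
    for (k in seq_len(n_folds)) {
      tr <- subset_epochs(ep, folds != k)
      te <- subset_epochs(ep, folds == k)
      fitted <- fit_pipeline(pipe, tr)
      sc <- score_metric(predict_pipeline(fitted, te), te$labels, metric)
      rows[[length(rows) + 1L]] <- data.frame(rep = r, fold = k, score = sc)
    }
  }
  folds_df <- do.call(rbind, rows)
  list(mean = mean(folds_df$score), folds = folds_df)
}
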
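#' Joint search space over BCI and classifier parameters
#'
#' The BCI parameters (feature-extraction time segment and CSP filter
#' count for synchronous data; window length and overlap for self-paced
#' data) are searched jointly with each classifier's hyperparameter grid,
#' since the best classifier setting depends on the feature space the BCI
#' parameters induce.
#'
#' @param feature_family `"bp"` or `"morlet"`.
#' @param time_segments list of `c(start_s, end_s)` candidates (synchronous;
#'   may be `list(NULL)` for self-paced windows).
#' @param csp_pairs vector of CSP pair counts; `NA` entries mean "no CSP".
#' @param window_configs list of [sliding_window_config()] candidates
#'   (self-paced only; `list(NULL)` otherwise).
#' @param classifier_grids named list `kind -> [param_grid()]`; defaults to
#'   [default_grid()] for each requested kind.
#' @param bands,morlet,morlet_prefilter passed through to [bci_pipeline()].
#' @return object of class `bci_search_space`.
#' @export
search_space <- function(feature_family = "bp",
                         time_segments = list(NULL),
                         csp_pairs = c(1, 2, 3),
                         window_configs = list(NULL),
                         classifier_grids = NULL,
                         bands = list(c(8, 12), c(16, 24)),
                         morlet = morlet_spec(),
                         morlet_prefilter = c(4, 30)) {
  if (is.null(classifier_grids))
    classifier_grids <- list(LDA = default_grid("LDA"))
  if (is.null(names(classifier_grids)) || any(names(classifier_grids) == ""))
    stop("classifier_grids must be a named list (kind -> grid)")
  if (!length(time_segments) || !length(csp_pairs) || !length(window_configs))
    stop("every search axis needs at least one candidate")
  structure(list(feature_family = feature_family,
                 time_segments = time_segments,
                 csp_pairs = csp_pairs,
                 window_configs = window_configs,
                 classifier_grids = classifier_grids,
                 bands = bands, morlet = morlet,
                 morlet_prefilter = morlet_prefilter),
            class = "bci_search_space")
}

# deterministic enumeration order: time segments as given, CSP pair counts
# ascending (NA = no CSP last), window configs as given, classifier kinds
# sorted, then each grid's expansion order. Ties in mean CV score resolve
# to the earliest config in this order, realizing the
# (earlier segment, fewer pairs, smaller params) tie-break.
enumerate_space <- function(space, seed = 1L) {
  csp_sorted <- space$csp_pairs[order(is.na(space$csp_pairs), space$csp_pairs)]
  configs <- list()
  for (ts in space$time_segments)
    for (np in csp_sorted)
      for (wc in space$window_configs)
        for (kind in sort(names(space$classifier_grids)))
          for (hp in grid_configs(space$classifier_grids[[kind]]))
            configs[[length(configs) + 1L]] <-
              list(feature_family = space$feature_family,
                   time_segment = ts,
                   n_csp_pairs = if (is.na(np)) NULL else np,
                   window_config = wc,
                   kind = kind, hyperparameters = hp,
                   bands = space$bands, morlet = space$morlet,
                   morlet_prefilter = space$morlet_prefilter,
                   seed = seed)
  configs
}

config_pipeline <- function(cfg) {
  bci_pipeline(feature_family = cfg$feature_family,
               bands = cfg$bands,
               time_segment = cfg$time_segment,
               n_csp_pairs = cfg$n_csp_pairs,
               morlet = cfg$morlet,
               morlet_prefilter = cfg$morlet_prefilter,
               classifier = classifier_spec(cfg$kind, cfg$hyperparameters,
                                            seed = cfg$seed))
}

config_id <- function(cfg) {
  seg <- if (is.null(cfg$time_segment)) "full"
         else sprintf("%g-%g", cfg$time_segment[1], cfg$time_segment[2])
  hp <- if (length(cfg$hyperparameters))
    paste(names(cfg$hyperparameters), unlist(cfg$hyperparameters),
          sep = "=", collapse = ",") else "default"
  sprintf("%s|seg=%s|csp=%s|%s|%s", cfg$feature_family, seg,
          cfg$n_csp_pairs %||% "none", cfg$kind, hp)
}

#' Exhaustive grid search by repeated cross-validation
#'
#' Evaluates every configuration in the space with [crossval_score()] and
#' returns the one with the best mean score. Ties resolve deterministically
#' to the earliest configuration in enumeration order (earlier time
#' segment, fewer CSP pairs, lexicographically smaller classifier
#' parameters).
#'
#' @param space a [search_space()].
#' @param ep training data: a labeled [epoch_set()] (cued trials or
#'   pre-built windows), or -- for self-paced searches over window
#'   parameters -- a list with elements `recording` and `control_intervals`
#'   from which windows are cut per candidate window config.
#' @param n_repeats,n_folds,seed cross-validation controls.
#' @param metric `"accuracy"` or `"auc"`.
#' @return list with `best_config`, `best_mean`, and `trace` (one row per
#'   config: `config`, `mean`, plus per-fold scores nested in
#'   `fold_scores`).
#' @export
grid_search <- function(space, ep, n_repeats = 5L, n_folds = 5L, seed = 1L,
                        metric = c("accuracy", "auc")) {
  stopifnot(inherits(space, "bci_search_space"))
  metric <- match.arg(metric)
  configs <- enumerate_space(space, seed = seed)
  if (!length(configs)) stop("empty search space")
  means <- numeric(length(configs))
  trace <- vector("list", length(configs))
  for (i in seq_along(configs)) {
    cv <- crossval_score(config_pipeline(configs[[i]]),
                         config_data(configs[[i]], ep),
                         n_repeats = n_repeats, n_folds = n_folds,
                         seed = seed, metric = metric)
    means[i] <- cv$mean
    trace[[i]] <- data.frame(config = config_id(configs[[i]]),
                             rep = cv$folds$rep, fold = cv$folds$fold,
                             score = cv$folds$score)
  }
  best <- which.max(means)   # first maximum = deterministic tie-break
  list(best_config = configs[[best]], best_mean = means[best],
       config_means = data.frame(
         config = vapply(configs, config_id, character(1)), mean = means),
       trace = do.call(rbind, trace))
}

# resolve the training material for one candidate config: epoch sets pass
# through; continuous self-paced data is windowed with the config's
# window parameters
config_data <- function(cfg, ep) {
  if (inherits(ep, "bci_epochs")) return(ep)
  if (is.list(ep) && !is.null(ep$recording)) {
    wc <- cfg$window_config %||% sliding_window_config()
    return(make_windows(ep$recording, ep$control_intervals, wc))
  }
  stop("training data must be an epoch set or a recording/intervals list")
}

#' Final refit on all training data and held-out evaluation
#'
#' Freezes every parameter at the selected configuration, refits the
#' pipeline on the full training set and scores it once on the independent
#' test set. Trial identifiers shared between training and test data are
#' treated as leakage and refused.
#'
#' @param cfg a configuration (as returned in `best_config` by
#'   [grid_search()]).
#' @param train_ep,test_ep disjoint training and test data; epoch sets, or
#'   `recording`/`control_intervals` lists for self-paced data (windowed
#'   with the config's window parameters).
#' @param metric `"accuracy"` or `"auc"`.
#' @return list with `score`, `predictions` (a [predict_proba()] result)
#'   and `fitted` (the frozen pipeline).
#' @export
fit_final_and_test <- function(cfg, train_ep, test_ep,
                               metric = c("accuracy", "auc")) {
  metric <- match.arg(metric)
  train_ep <- config_data(cfg, train_ep)
  test_ep <- config_data(cfg, test_ep)
  shared <- intersect(train_ep$trial_ids, test_ep$trial_ids)
  if (length(shared))
    stop("train/test leakage: ", length(shared),
         " shared trial identifiers (e.g. '", shared[1], "')")
  fitted <- fit_pipeline(config_pipeline(cfg), train_ep)
  pred <- predict_pipeline(fitted, test_ep)
  list(score = score_metric(pred, test_ep$labels, metric),
       predictions = pred, fitted = fitted)
}
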
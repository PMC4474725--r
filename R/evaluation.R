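#' Classification accuracy
#'
#' @param predicted,truth equal-length label vectors.
#' @return fraction of equal entries in `[0, 1]`.
#' @export
accuracy <- function(predicted, truth) {
  if (!length(truth)) stop("empty label vectors")
  if (length(predicted) != length(truth))
    stop("predicted and truth lengths differ")
  mean(as.character(predicted) == as.character(truth))
}

#' Sliding-window configuration for self-paced evaluation
#'
#' @param window_length_s window length in seconds (> 0).
#' @param overlap_fraction overlap between consecutive windows in `[0, 1)`;
#'   the stride is `window_length * (1 - overlap)` and must be at least one
#'   sample at application time.
#' @return object of class `bci_window_config`.
#' @export
sliding_window_config <- function(window_length_s = 2, overlap_fraction = 0.5) {
  if (window_length_s <= 0) stop("window_length_s must be positive")
  if (overlap_fraction < 0 || overlap_fraction >= 1)
    stop("overlap_fraction must lie in [0, 1)")
  structure(list(window_length_s = as.numeric(window_length_s),
                 overlap_fraction = as.numeric(overlap_fraction)),
            class = "bci_window_config")
}

#' Cut a continuous recording into labeled sliding windows
#'
#' Static classifiers are applied to the sequential self-paced problem by
#' sliding half-open windows over the recording at a fixed stride. A window
#' is labeled `"control"` when at least half of its samples fall inside any
#' control interval, `"nc"` otherwise (majority rule; the tie at exactly
#' 50 % counts as control).
#'
#' @param rec a [recording()].
#' @param control_intervals data.frame with 0-based half-open
#'   `start_sample` / `end_sample` columns ([generate_selfpaced()]).
#' @param config a [sliding_window_config()].
#' @return a [epoch_set()] of windows with labels `"control"` / `"nc"` and
#'   attribute `window_starts` (0-based start sample per window).
#' @export
make_windows <- function(rec, control_intervals, config) {
  stopifnot(inherits(rec, "bci_recording"),
            inherits(config, "bci_window_config"))
  fs <- rec$sampling_rate
  w <- as.integer(round_half_up(config$window_length_s * fs))
  if (w > n_samples(rec)) stop("window longer than the recording")
  step <- as.integer(round_half_up(w * (1 - config$overlap_fraction)))
  if (step < 1L) stop("window stride below one sample; reduce overlap")
  starts <- seq.int(0L, n_samples(rec) - w, by = step)
  inside <- rep(FALSE, n_samples(rec))
  for (k in seq_len(nrow(control_intervals))) {
    a <- control_intervals$start_sample[k]
    b <- control_intervals$end_sample[k]
    if (b > a) inside[(a + 1L):b] <- TRUE
  }
  cum <- c(0L, cumsum(inside))
  frac <- (cum[starts + w + 1L] - cum[starts + 1L]) / w
  labels <- ifelse(frac >= 0.5, "control", "nc")
  arr <- array(0, dim = c(length(starts), nrow(rec$signals), w))
  for (i in seq_along(starts))
    arr[i, , ] <- rec$signals[, (starts[i] + 1L):(starts[i] + w), drop = FALSE]
  ep <- epoch_set(arr, labels, fs, window = c(0, config$window_length_s),
                  channel_labels = rec$channel_labels,
                  trial_ids = sprintf("%s_w%06d", rec$id, starts))
  attr(ep, "window_starts") <- starts
  ep
}

#' ROC curve over swept decision thresholds
#'
#' Sweeps thresholds over the distinct score values (plus an initial
#' all-negative point) and returns the monotone staircase from `(0, 0)` to
#' `(1, 1)`. Tied scores advance FPR and TPR simultaneously, producing the
#' diagonal segments whose trapezoidal area realizes the half-credit tie
#' convention of the Mann-Whitney statistic.
#'
#' @param scores numeric vector of positive-class scores.
#' @param labels binary labels.
#' @param positive which label is the positive class (default `"control"`).
#' @return data.frame with columns `threshold`, `fpr`, `tpr`.
#' @export
roc_curve <- function(scores, labels, positive = "control") {
  if (length(scores) != length(labels)) stop("scores/labels length mismatch")
  pos <- labels == positive
  if (!any(pos) || all(pos))
    stop("ROC needs both classes present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  p <- pos[ord]
  # group ties: cumulative counts at the last index of each distinct score
  last <- which(c(diff(s) != 0, TRUE))
  tp <- cumsum(p)[last]
  fp <- cumsum(!p)[last]
  data.frame(threshold = c(Inf, s[last]),
             fpr = c(0, fp / sum(!pos)),
             tpr = c(0, tp / sum(pos)))
}

#' Area under the ROC curve
#'
#' Trapezoidal area under [roc_curve()]; equal to the normalized
#' Mann-Whitney U statistic with half credit for ties -- the probability
#' that a random positive sample outranks a random negative one.
#'
#' @inheritParams roc_curve
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, labels, positive = "control") {
  rc <- roc_curve(scores, labels, positive)
  sum(diff(rc$fpr) * (utils::head(rc$tpr, -1) + utils::tail(rc$tpr, -1)) / 2)
}
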
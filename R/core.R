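#' Continuous multichannel EEG recording with event markers
#'
#' A `bci_recording` bundles a channels-by-samples signal matrix (amplitudes
#' in microvolts), its sampling rate, channel labels, and a marker table of
#' cue events. Sample indexing is 0-based throughout: a marker with
#' `onset_sample = 0` refers to the first column of `signals`.
#'
#' @param signals numeric matrix, channels x samples, in microvolts.
#' @param sampling_rate sampling rate in Hz (> 0).
#' @param channel_labels character vector naming each row of `signals`.
#' @param markers data.frame with columns `onset_sample` (0-based integer),
#'   `label` (character class identifier) and `duration_samples`
#'   (non-negative integer, 0 for instantaneous cues). May have zero rows.
#' @param id optional string identifying the recording (used for provenance
#'   and train/test leakage checks downstream).
#'
#' @return an object of class `bci_recording`.
#' @export
recording <- function(signals, sampling_rate, channel_labels = NULL,
                      markers = empty_markers(), id = "recording") {
  signals <- as.matrix(signals)
  storage.mode(signals) <- "double"
  if (is.null(channel_labels)) {
    channel_labels <- rownames(signals)
    if (is.null(channel_labels))
      channel_labels <- sprintf("ch%02d", seq_len(nrow(signals)))
  }
  if (length(channel_labels) != nrow(signals))
    stop("channel_labels length (", length(channel_labels),
         ") must equal channel count (", nrow(signals), ")")
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L || sampling_rate <= 0)
    stop("sampling_rate must be a single positive number")
  markers <- validate_markers(markers, ncol(signals))
  rownames(signals) <- channel_labels
  structure(
    list(signals = signals, sampling_rate = as.numeric(sampling_rate),
         channel_labels = as.character(channel_labels), markers = markers,
         id = as.character(id)),
    class = "bci_recording")
}

#' Construct a marker table
#'
#' @param onset_sample 0-based sample indices of cue onsets.
#' @param label class identifier per marker.
#' @param duration_samples event durations in samples (default 0).
#' @return data.frame with the three marker columns.
#' @export
markers_table <- function(onset_sample, label, duration_samples = 0L) {
  data.frame(onset_sample = as.integer(onset_sample),
             label = as.character(label),
             duration_samples = as.integer(rep_len(duration_samples,
                                                   length(onset_sample))),
             stringsAsFactors = FALSE)
}

empty_markers <- function() markers_table(integer(0), character(0), integer(0))

validate_markers <- function(markers, n_samples) {
  req <- c("onset_sample", "label", "duration_samples")
  if (!is.data.frame(markers) || !all(req %in% names(markers)))
    stop("markers must be a data.frame with columns ",
         paste(req, collapse = ", "))
  markers <- markers[, req, drop = FALSE]
  markers$onset_sample <- as.integer(markers$onset_sample)
  markers$label <- as.character(markers$label)
  markers$duration_samples <- as.integer(markers$duration_samples)
  if (nrow(markers)) {
    if (any(markers$onset_sample < 0L) || any(markers$onset_sample >= n_samples))
      stop("marker onsets must lie within [0, sample_count)")
    if (any(markers$duration_samples < 0L))
      stop("marker durations must be non-negative")
    if (any(markers$onset_sample + markers$duration_samples > n_samples))
      stop("marker onset + duration exceeds recording length")
  }
  rownames(markers) <- NULL
  markers
}

#' @export
print.bci_recording <- function(x, ...) {
  cat(sprintf("<bci_recording '%s'> %d channels x %d samples @ %g Hz, %d markers\n",
              x$id, nrow(x$signals), ncol(x$signals), x$sampling_rate,
              nrow(x$markers)))
  invisible(x)
}

n_samples <- function(rec) ncol(rec$signals)

#' Set of epoched trials
#'
#' An `epoch_set` holds a trials x channels x samples array with one class
#' label per trial. All epochs share a common length and channel ordering.
#'
#' @param epochs 3-d numeric array (trial, channel, sample).
#' @param labels character vector of class identifiers, one per trial.
#' @param sampling_rate Hz.
#' @param window numeric length-2, epoch window in seconds relative to the cue.
#' @param channel_labels optional channel names.
#' @param trial_ids optional unique identifiers per trial (provenance; used by
#'   leakage checks).
#' @return object of class `bci_epochs`.
#' @export
epoch_set <- function(epochs, labels, sampling_rate, window = c(NA_real_, NA_real_),
                      channel_labels = NULL, trial_ids = NULL) {
  if (length(dim(epochs)) != 3L)
    stop("epochs must be a 3-d array (trial x channel x sample)")
  if (dim(epochs)[1] != length(labels))
    stop("labels length must equal trial count")
  if (!all(is.na(window)) && window[2] <= window[1])
    stop("window end must exceed window start")
  if (is.null(channel_labels))
    channel_labels <- sprintf("ch%02d", seq_len(dim(epochs)[2]))
  if (is.null(trial_ids))
    trial_ids <- sprintf("trial%04d", seq_len(dim(epochs)[1]))
  structure(
    list(epochs = epochs, labels = as.character(labels),
         sampling_rate = as.numeric(sampling_rate),
         window = as.numeric(window),
         channel_labels = as.character(channel_labels),
         trial_ids = as.character(trial_ids)),
    class = "bci_epochs")
}

#' @export
print.bci_epochs <- function(x, ...) {
  d <- dim(x$epochs)
  cat(sprintf("<bci_epochs> %d trials x %d channels x %d samples @ %g Hz\n",
              d[1], d[2], d[3], x$sampling_rate))
  tb <- table(x$labels)
  cat("  classes:", paste(sprintf("%s(%d)", names(tb), tb), collapse = ", "), "\n")
  invisible(x)
}

n_trials <- function(ep) dim(ep$epochs)[1]
n_channels <- function(ep) dim(ep$epochs)[2]
epoch_length <- function(ep) dim(ep$epochs)[3]

# round half away from zero, so that seconds -> samples is unambiguous
# across platforms (base round() rounds half to even)
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Extract cue-aligned epochs from a continuous recording
#'
#' Cuts one epoch per marker whose label appears in `label_map`, covering the
#' half-open sample range `[onset + round(start_s * fs), onset + round(end_s * fs))`
#' (0-based; seconds are converted with round-half-away-from-zero). Markers
#' with labels absent from `label_map` are dropped.
#'
#' @param rec a [recording()].
#' @param window_start_s,window_end_s epoch window in seconds relative to each
#'   cue onset; `window_end_s > window_start_s`. Negative starts reach into
#'   pre-cue signal.
#' @param label_map named character vector mapping marker labels to class
#'   identifiers, e.g. `c("769" = "left", "770" = "right")`. `NULL` keeps
#'   every marker under its own label.
#' @return a [epoch_set()] with one epoch per retained marker.
#' @export
extract_epochs <- function(rec, window_start_s, window_end_s, label_map = NULL) {
  stopifnot(inherits(rec, "bci_recording"))
  if (window_end_s <= window_start_s)
    stop("window_end_s (", window_end_s, ") must exceed window_start_s (",
         window_start_s, ")")
  mk <- rec$markers
  if (is.null(label_map)) {
    label_map <- unique(mk$label)
    names(label_map) <- label_map
  }
  keep <- mk$label %in% names(label_map)
  mk <- mk[keep, , drop = FALSE]
  if (!nrow(mk)) stop("no markers retained by label_map")
  fs <- rec$sampling_rate
  s0 <- as.integer(round_half_up(window_start_s * fs))
  s1 <- as.integer(round_half_up(window_end_s * fs))
  len <- s1 - s0
  if (len < 1L) stop("epoch window shorter than one sample")
  starts <- mk$onset_sample + s0                 # 0-based inclusive
  ends <- mk$onset_sample + s1                   # 0-based exclusive
  bad <- which(starts < 0L | ends > n_samples(rec))
  if (length(bad))
    stop("epoch window [", window_start_s, ", ", window_end_s,
         ") s extends past recording bounds for marker at sample ",
         mk$onset_sample[bad[1]], " (label '", mk$label[bad[1]], "')")
  nt <- nrow(mk)
  arr <- array(0, dim = c(nt, nrow(rec$signals), len))
  for (i in seq_len(nt))
    arr[i, , ] <- rec$signals[, (starts[i] + 1L):ends[i], drop = FALSE]
  epoch_set(arr, labels = unname(label_map[mk$label]), sampling_rate = fs,
            window = c(window_start_s, window_end_s),
            channel_labels = rec$channel_labels,
            trial_ids = sprintf("%s_t%05d", rec$id, which(keep)))
}

#' Remove the per-trial per-channel mean
#'
#' Standardizes epochs by mean removal only (no variance scaling), so that
#' after band-pass filtering the signal variance equals its band power --
#' the quantity CSP discriminates on.
#'
#' @param ep a [epoch_set()].
#' @return the centered epoch set. Idempotent.
#' @export
center_epochs <- function(ep) {
  stopifnot(inherits(ep, "bci_epochs"))
  m <- apply(ep$epochs, c(1, 2), mean)
  ep$epochs <- ep$epochs - as.vector(m)  # recycles over the 3rd dimension
  ep
}

#' Crop epochs to a sub-window
#'
#' Restricts every epoch to `[start_s, end_s)` measured relative to the
#' epoch's own window origin (the cue position used at extraction time).
#'
#' @param ep a [epoch_set()].
#' @param start_s,end_s sub-window in seconds relative to the cue.
#' @return cropped epoch set.
#' @export
crop_epochs <- function(ep, start_s, end_s) {
  stopifnot(inherits(ep, "bci_epochs"))
  if (end_s <= start_s) stop("end_s must exceed start_s")
  fs <- ep$sampling_rate
  org <- ep$window[1]
  if (is.na(org)) org <- 0
  i0 <- as.integer(round_half_up((start_s - org) * fs))
  i1 <- as.integer(round_half_up((end_s - org) * fs))
  if (i0 < 0L || i1 > epoch_length(ep))
    stop("crop window [", start_s, ", ", end_s, ") s outside epoch window")
  if (i1 - i0 < 1L) stop("crop window shorter than one sample")
  ep$epochs <- ep$epochs[, , (i0 + 1L):i1, drop = FALSE]
  ep$window <- c(start_s, end_s)
  ep
}

#' Subset trials of an epoch set
#' @param ep a [epoch_set()].
#' @param idx integer or logical trial index.
#' @return epoch set with the selected trials.
#' @export
subset_epochs <- function(ep, idx) {
  stopifnot(inherits(ep, "bci_epochs"))
  ep$epochs <- ep$epochs[idx, , , drop = FALSE]
  ep$labels <- ep$labels[idx]
  ep$trial_ids <- ep$trial_ids[idx]
  ep
}
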
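#' Configuration for synthetic motor-imagery EEG
#'
#' Describes band-limited oscillatory sources whose power is attenuated
#' (event-related desynchronization, ERD) or enhanced (ERS) depending on
#' the imagined class, mixed linearly into EEG channels with additive white
#' noise. Sources are band-pass-filtered Gaussian noise rather than pure
#' sinusoids, so downstream spatial filtering faces realistic
#' broadband-in-band variance.
#'
#' The defaults emulate a two-class (left vs right hand) montage of 10
#' channels over the sensorimotor strip at 250 Hz: two lateralized alpha
#' (8-12 Hz) sources showing contralateral ERD with factor 0.3, one
#' midline beta (16-24 Hz) source, 4 s trials, and 5 microvolt sensor noise.
#'
#' @param n_channels number of EEG channels.
#' @param sampling_rate Hz.
#' @param classes class identifiers (rows of `modulation`).
#' @param trials_per_class trials generated per class.
#' @param trial_length_s trial duration in seconds.
#' @param source_bands list of `c(low_hz, high_hz, base_amplitude)` per
#'   source; amplitude is the source's standard deviation in microvolts.
#' @param modulation classes x sources matrix of multiplicative power
#'   factors (1 = no change, < 1 = ERD, > 1 = ERS). Amplitudes scale by
#'   `sqrt(factor)` since ERD is defined on power.
#' @param mixing channels x sources weight matrix with full column rank.
#' @param noise_sd white sensor-noise standard deviation, microvolts.
#' @param inter_trial_gap_s unmodulated gap preceding each trial.
#' @param seed global integer seed; per-trial streams are derived from it
#'   (see Details).
#'
#' @details Per-trial randomness uses derived seeds
#' `(seed + 1000003 * trial_index) mod (2^31 - 1)`, so changing the trial
#' count never reshuffles the signal streams of earlier trials.
#'
#' @return object of class `bci_synth_config`.
#' @export
synth_config <- function(n_channels = 10,
                         sampling_rate = 250,
                         classes = c("left", "right"),
                         trials_per_class = 100,
                         trial_length_s = 4,
                         source_bands = list(c(8, 12, 10), c(8, 12, 10),
                                             c(16, 24, 6)),
                         modulation = rbind(left = c(1, 0.3, 1),
                                            right = c(0.3, 1, 1)),
                         mixing = NULL,
                         noise_sd = 5,
                         inter_trial_gap_s = 1,
                         seed = 1L) {
  modulation <- as.matrix(modulation)
  if (nrow(modulation) != length(classes) ||
      ncol(modulation) != length(source_bands))
    stop("modulation must be classes x sources (",
         length(classes), " x ", length(source_bands), ")")
  if (any(modulation < 0)) stop("modulation factors must be >= 0")
  if (is.null(mixing))
    mixing <- default_mixing(n_channels, length(source_bands))
  mixing <- as.matrix(mixing)
  if (nrow(mixing) != n_channels || ncol(mixing) != length(source_bands))
    stop("mixing must be channels x sources")
  if (qr(mixing)$rank < ncol(mixing))
    stop("mixing matrix is rank-deficient")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  rownames(modulation) <- classes
  structure(list(n_channels = as.integer(n_channels),
                 sampling_rate = as.numeric(sampling_rate),
                 classes = as.character(classes),
                 trials_per_class = as.integer(trials_per_class),
                 trial_length_s = as.numeric(trial_length_s),
                 source_bands = source_bands,
                 modulation = modulation, mixing = mixing,
                 noise_sd = as.numeric(noise_sd),
                 inter_trial_gap_s = as.numeric(inter_trial_gap_s),
                 seed = as.integer(seed)),
            class = "bci_synth_config")
}

# smooth lateralized spatial profiles: source s projects mainly onto a
# cluster of channels centred at an evenly spaced scalp position
default_mixing <- function(n_channels, n_sources) {
  centers <- seq(1, n_channels, length.out = n_sources + 2)[-c(1, n_sources + 2)]
  sapply(seq_len(n_sources), function(s)
    exp(-((seq_len(n_channels) - centers[s])^2) / (2 * (n_channels / 6)^2)))
}

derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) + 1000003 * as.numeric(index)) %% 2147483647)
}

# band-limited Gaussian noise with exact target standard deviation
band_limited_noise <- function(n, band, fs, sd_target) {
  x <- stats::rnorm(n + 2L)           # margin against pathological sd = 0
  bf <- design_bandpass(band_spec(band[1], band[2]), fs, 5L)
  y <- filtfilt_mat(bf, matrix(x, ncol = 1))[seq_len(n), 1]
  s <- stats::sd(y)
  if (s < 1e-12) s <- 1
  y * (sd_target / s)
}

#' Generate a synchronous (cued-trial) synthetic recording
#'
#' Produces a continuous recording of cued trials in randomized class
#' order. During each trial, source `s` oscillates in its band with power
#' scaled by `modulation[class, s]`; sources are mixed into channels and
#' white Gaussian noise is added. Each trial is preceded by an unmodulated
#' inter-trial gap, and a marker is placed at each trial onset. Identical
#' seeds give bit-identical output.
#'
#' @param config a [synth_config()].
#' @return a [recording()] with one marker per trial.
#' @export
generate_synchronous <- function(config) {
  stopifnot(inherits(config, "bci_synth_config"))
  fs <- config$sampling_rate
  n_trial <- as.integer(round_half_up(config$trial_length_s * fs))
  n_gap <- as.integer(round_half_up(config$inter_trial_gap_s * fs))
  n_tot_trials <- config$trials_per_class * length(config$classes)
  class_seq <- rep(config$classes, each = config$trials_per_class)
  class_seq <- with_seed(config$seed, sample(class_seq))
  seg_len <- n_gap + n_trial
  signals <- matrix(0, config$n_channels, n_tot_trials * seg_len)
  onsets <- integer(n_tot_trials)
  ones <- rep(1, length(config$source_bands))
  for (i in seq_len(n_tot_trials)) {
    seg <- with_seed(derive_seed(config$seed, i),
                     synth_segment(config, seg_len,
                                   gap_factors = ones, gap_len = n_gap,
                                   factors = config$modulation[class_seq[i], ]))
    col0 <- (i - 1L) * seg_len
    signals[, (col0 + 1L):(col0 + seg_len)] <- seg
    onsets[i] <- col0 + n_gap           # 0-based onset of the modulated part
  }
  recording(signals, fs,
            channel_labels = sprintf("ch%02d", seq_len(config$n_channels)),
            markers = markers_table(onsets, class_seq, n_trial),
            id = sprintf("synth_sync_seed%d", config$seed))
}

# one contiguous segment: unmodulated gap followed by a modulated stretch
synth_segment <- function(config, seg_len, gap_factors, gap_len, factors) {
  fs <- config$sampling_rate
  S <- sapply(seq_along(config$source_bands), function(s) {
    b <- config$source_bands[[s]]
    src <- band_limited_noise(seg_len, b[1:2], fs, b[3])
    gain <- c(rep(sqrt(gap_factors[s]), gap_len),
              rep(sqrt(factors[s]), seg_len - gap_len))
    src * gain
  })
  X <- config$mixing %*% t(S)
  if (config$noise_sd > 0)
    X <- X + matrix(stats::rnorm(length(X), sd = config$noise_sd), nrow(X))
  X
}

#' Configuration for self-paced (continuous) synthetic EEG
#'
#' Extends [synth_config()] with a continuous-stream layout: alternating
#' No-Control (NC) and control stretches whose lengths are drawn uniformly
#' from `control_interval_range_s` (the default 1.5-8 s matches the
#' interval statistics of published self-paced motor-imagery recordings).
#' ERD/ERS modulation is applied only inside control intervals, using the
#' modulation row of `control_class`; NC stretches are unmodulated.
#'
#' @param base a [synth_config()] supplying channels, sources, modulation,
#'   mixing and noise.
#' @param control_interval_range_s length-2 `(min, max)` seconds for both
#'   control and NC stretch lengths.
#' @param total_length_s total recording length in seconds.
#' @param control_class which modulation row drives control periods
#'   (default: first class).
#' @return object of class `bci_selfpaced_config`.
#' @export
selfpaced_config <- function(base = synth_config(),
                             control_interval_range_s = c(1.5, 8),
                             total_length_s = 240,
                             control_class = NULL) {
  r <- control_interval_range_s
  if (r[1] > r[2]) stop("control_interval_range_s must satisfy min <= max")
  if (total_length_s <= r[2])
    stop("total_length_s must exceed the maximum interval length")
  if (is.null(control_class)) control_class <- base$classes[1]
  if (!control_class %in% base$classes)
    stop("control_class '", control_class, "' not among config classes")
  structure(c(unclass(base),
              list(control_interval_range_s = as.numeric(r),
                   total_length_s = as.numeric(total_length_s),
                   control_class = control_class)),
            class = c("bci_selfpaced_config", "bci_synth_config"))
}

#' Generate a self-paced synthetic recording with No-Control periods
#'
#' Alternates NC and control stretches (starting with NC) with lengths
#' drawn uniformly from the configured range; the final stretch is
#' truncated so that control and NC samples account exactly for the total
#' length. Control-interval modulation multiplies the source amplitude by
#' the square root of the class's power factor inside each interval.
#'
#' @param config a [selfpaced_config()].
#' @return list with `recording` (a [recording()]) and `control_intervals`
#'   (data.frame of half-open, sorted, non-overlapping 0-based
#'   `start_sample` / `end_sample` rows).
#' @export
generate_selfpaced <- function(config) {
  stopifnot(inherits(config, "bci_selfpaced_config"))
  fs <- config$sampling_rate
  n_total <- as.integer(round_half_up(config$total_length_s * fs))
  r <- config$control_interval_range_s
  layout <- with_seed(config$seed, {
    lens <- integer(0)
    acc <- 0L
    while (acc < n_total) {
      l <- as.integer(round_half_up(stats::runif(1, r[1], r[2]) * fs))
      l <- min(l, n_total - acc)
      lens <- c(lens, l)
      acc <- acc + l
    }
    lens
  })
  is_control <- rep(c(FALSE, TRUE), length.out = length(layout))
  # the final stretch is truncated by the total length; if that leaves a
  # control interval shorter than the configured minimum, emit it as NC so
  # every reported control interval respects the range
  n_last <- length(layout)
  if (is_control[n_last] && layout[n_last] < round_half_up(r[1] * fs))
    is_control[n_last] <- FALSE
  ends <- cumsum(layout)
  starts <- c(0L, ends[-length(ends)])
  gain <- rep(1, n_total)
  factors <- config$modulation[config$control_class, ]
  ctrl <- data.frame(start_sample = starts[is_control],
                     end_sample = ends[is_control])
  signals <- with_seed(derive_seed(config$seed, 0L), {
    S <- sapply(seq_along(config$source_bands), function(s) {
      b <- config$source_bands[[s]]
      src <- band_limited_noise(n_total, b[1:2], fs, b[3])
      g <- rep(1, n_total)
      for (k in seq_len(nrow(ctrl)))
        g[(ctrl$start_sample[k] + 1L):ctrl$end_sample[k]] <- sqrt(factors[s])
      src * g
    })
    X <- config$mixing %*% t(S)
    if (config$noise_sd > 0)
      X <- X + matrix(stats::rnorm(length(X), sd = config$noise_sd), nrow(X))
    X
  })
  rec <- recording(signals, fs,
                   channel_labels = sprintf("ch%02d", seq_len(config$n_channels)),
                   id = sprintf("synth_selfpaced_seed%d", config$seed))
  list(recording = rec, control_intervals = ctrl)
}
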
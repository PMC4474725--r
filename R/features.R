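#' Labeled feature matrix
#'
#' Samples-by-features matrix with per-column provenance names and one class
#' label per row. Row order always matches the trial order of the epoch set
#' the features were extracted from.
#'
#' @param values numeric matrix, samples x features.
#' @param feature_names unique column names recording band / channel /
#'   transform provenance.
#' @param labels class label per row.
#' @param trial_ids optional per-row identifiers (leakage checks).
#' @return object of class `bci_features`.
#' @export
feature_matrix <- function(values, feature_names, labels, trial_ids = NULL) {
  values <- as.matrix(values)
  if (length(feature_names) != ncol(values))
    stop("feature_names length must equal feature count")
  if (anyDuplicated(feature_names)) stop("feature names must be unique")
  if (length(labels) != nrow(values))
    stop("labels length must equal row count")
  if (!all(is.finite(values))) stop("non-finite feature values")
  colnames(values) <- feature_names
  if (is.null(trial_ids)) trial_ids <- sprintf("row%04d", seq_len(nrow(values)))
  structure(list(values = values, feature_names = as.character(feature_names),
                 labels = as.character(labels),
                 trial_ids = as.character(trial_ids)),
            class = "bci_features")
}

#' @export
print.bci_features <- function(x, ...) {
  cat(sprintf("<bci_features> %d samples x %d features, %d classes\n",
              nrow(x$values), ncol(x$values), length(unique(x$labels))))
  invisible(x)
}

#' Export features as CSV (feature columns + trailing label column)
#' @param fm a [feature_matrix()].
#' @param path output CSV path.
#' @export
write_features_csv <- function(fm, path) {
  df <- as.data.frame(fm$values)
  df$label <- fm$labels
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Band power of a signal segment
#'
#' Time-normalized sum of squares: `mean(x^2)`. Using the mean rather than
#' the raw sum makes features comparable across candidate time segments of
#' different lengths during model selection; classifiers are unaffected by
#' the monotone rescaling.
#'
#' @param x numeric vector (single-channel segment, microvolts).
#' @return power in microvolts squared.
#' @export
band_power <- function(x) {
  if (!length(x)) stop("empty segment")
  mean(x^2)
}

# log with clamp: band-pass-filtered all-zero segments have power 0
log_power <- function(p) log(pmax(p, 1e-12))

#' Band-power features from filter-bank output
#'
#' For every trial, band and (surrogate) channel, computes the band power
#' and its natural logarithm, giving `2 * bands * channels` features per
#' trial. Inputs are the per-band filtered (and typically CSP-projected)
#' epoch sets returned by [apply_filterbank()].
#'
#' @param band_epochs named list of [epoch_set()]s, one per band, sharing
#'   trials and labels.
#' @return a [feature_matrix()].
#' @export
bp_features <- function(band_epochs) {
  if (!length(band_epochs)) stop("no bands supplied")
  nt <- n_trials(band_epochs[[1]])
  labs <- band_epochs[[1]]$labels
  ids <- band_epochs[[1]]$trial_ids
  for (be in band_epochs) {
    if (n_trials(be) != nt || !identical(be$labels, labs))
      stop("band epoch sets have inconsistent trials or labels")
  }
  if (is.null(names(band_epochs)))
    names(band_epochs) <- sprintf("band%d", seq_along(band_epochs))
  cols <- list()
  cnames <- character(0)
  for (bn in names(band_epochs)) {
    be <- band_epochs[[bn]]
    nc <- n_channels(be)
    pw <- t(apply(be$epochs, 1, function(tr)
      rowMeans(matrix(tr, nrow = nc)^2)))
    if (nc == 1L) pw <- matrix(pw, ncol = 1L)
    cols[[length(cols) + 1L]] <- pw
    cols[[length(cols) + 1L]] <- log_power(pw)
    cnames <- c(cnames,
                sprintf("%s:%s:power", bn, be$channel_labels),
                sprintf("%s:%s:logpower", bn, be$channel_labels))
  }
  feature_matrix(do.call(cbind, cols), cnames, labs, trial_ids = ids)
}

#' Morlet wavelet specification
#'
#' @param center_frequencies strictly increasing centers in Hz. The default
#'   26 centers at 1 Hz spacing, 4.5 to 29.5 Hz, tile the 4-30 Hz range of
#'   sensory-motor rhythms with 1-Hz bands.
#' @param cycles wavelet width in cycles (default 7).
#' @return object of class `bci_morlet_spec`.
#' @export
morlet_spec <- function(center_frequencies = seq(4.5, 29.5, by = 1),
                        cycles = 7) {
  f <- as.numeric(center_frequencies)
  if (any(diff(f) <= 0)) stop("center frequencies must be strictly increasing")
  if (any(f <= 0)) stop("center frequencies must be positive")
  if (cycles <= 0) stop("cycles must be positive")
  structure(list(center_frequencies = f, cycles = as.numeric(cycles)),
            class = "bci_morlet_spec")
}

# unit-energy complex Morlet wavelet sampled at fs, truncated at 3.5 sd
morlet_wavelet <- function(f, cycles, fs) {
  sd_t <- cycles / (2 * pi * f)
  half <- ceiling(3.5 * sd_t * fs)
  t <- (-half:half) / fs
  w <- exp(-t^2 / (2 * sd_t^2)) * exp(1i * 2 * pi * f * t)
  w / sqrt(sum(Mod(w)^2))
}

# 'same' complex convolution via FFT, columns of X against kernel w
conv_same_mat <- function(X, w) {
  n <- nrow(X)
  m <- length(w)
  nf <- stats::nextn(n + m - 1L, 2)
  W <- stats::fft(c(w, rep(0, nf - m)))
  off <- (m - 1L) %/% 2L
  apply(X, 2, function(col) {
    y <- stats::fft(stats::fft(c(col, rep(0, nf - n))) * W, inverse = TRUE) / nf
    y[(off + 1L):(off + n)]
  })
}

#' Morlet wavelet band-power features
#'
#' Convolves every trial/channel series with unit-energy complex Morlet
#' wavelets at the spec's center frequencies and takes the time-averaged
#' squared magnitude, giving `length(center_frequencies) * channels`
#' features per trial (26 per channel with the default spec).
#'
#' @param ep a [epoch_set()] (typically broad-band filtered first).
#' @param spec a [morlet_spec()].
#' @param log if `TRUE`, append the log of every power feature as well.
#' @return a [feature_matrix()].
#' @export
morlet_features <- function(ep, spec = morlet_spec(), log = FALSE) {
  stopifnot(inherits(ep, "bci_epochs"), inherits(spec, "bci_morlet_spec"))
  d <- dim(ep$epochs)
  fs <- ep$sampling_rate
  lowest <- spec$center_frequencies[1]
  wlen <- 2L * ceiling(3.5 * spec$cycles / (2 * pi * lowest) * fs) + 1L
  if (wlen > d[3])
    stop("epoch length ", d[3], " shorter than the ", lowest,
         " Hz wavelet support (", wlen, " samples)")
  flat <- matrix(aperm(ep$epochs, c(3, 2, 1)), nrow = d[3])  # samples x (ch*trial)
  pw <- matrix(0, nrow = d[1], ncol = 0)
  for (f in spec$center_frequencies) {
    w <- morlet_wavelet(f, spec$cycles, fs)
    amp2 <- Mod(conv_same_mat(flat, w))^2
    # mean over time per trial/channel -> trials x channels
    m <- matrix(colMeans(amp2), nrow = d[2])
    pw <- cbind(pw, t(m))
  }
  cnames <- as.vector(outer(ep$channel_labels, spec$center_frequencies,
                            function(ch, f) sprintf("morlet%0.1f:%s:power", f, ch)))
  # outer() varies channels fastest; pw columns vary channels fastest per freq
  vals <- pw
  names_out <- cnames
  if (log) {
    vals <- cbind(vals, log_power(pw))
    names_out <- c(names_out, sub(":power$", ":logpower", cnames))
  }
  feature_matrix(vals, names_out, ep$labels, trial_ids = ep$trial_ids)
}
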
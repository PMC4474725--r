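#' Band-pass specification and filter banks
#'
#' A filter bank is an ordered array of Butterworth band-pass blocks; each
#' block isolates one frequency sub-band of the signal. The default order is
#' 5, giving a maximally flat pass band.
#'
#' @param low_hz,high_hz band edges in Hz, `0 < low_hz < high_hz`.
#' @return `band_spec()` returns a length-2 numeric band; `filter_bank()` an
#'   object of class `bci_filterbank`.
#' @export
band_spec <- function(low_hz, high_hz) {
  if (!(low_hz > 0 && high_hz > low_hz))
    stop("need 0 < low_hz < high_hz, got (", low_hz, ", ", high_hz, ")")
  c(low_hz = low_hz, high_hz = high_hz)
}

#' @rdname band_spec
#' @param bands list of bands (each a [band_spec()] or `c(low, high)` pair).
#' @param order Butterworth order per block (default 5).
#' @export
filter_bank <- function(bands = list(c(8, 12), c(16, 24)), order = 5L) {
  if (!length(bands)) stop("a filter bank needs at least one band")
  if (order < 1L) stop("order must be >= 1")
  bands <- lapply(bands, function(b) band_spec(b[[1]], b[[2]]))
  structure(list(bands = bands, order = as.integer(order)),
            class = "bci_filterbank")
}

#' Design a Butterworth band-pass filter
#'
#' The filter is designed analytically in zero-pole-gain form (Butterworth
#' low-pass prototype, low-pass to band-pass transform, bilinear transform
#' with pre-warped edges) and stored as cascaded second-order sections,
#' which keeps high-order narrow-band designs numerically stable.
#'
#' @param band a [band_spec()].
#' @param sampling_rate Hz; both edges must lie below Nyquist.
#' @param order Butterworth order (default 5).
#' @return object of class `bci_bandpass` holding the second-order sections.
#' @export
design_bandpass <- function(band, sampling_rate, order = 5L) {
  low <- band[[1]]; high <- band[[2]]
  if (high <= low || low <= 0)
    stop("invalid band (", low, ", ", high, ")")
  if (high >= sampling_rate / 2)
    stop("band edge ", high, " Hz reaches Nyquist (",
         sampling_rate / 2, " Hz)")
  n <- as.integer(order)
  # analog low-pass prototype poles on the unit circle
  k <- seq_len(n)
  p <- exp(1i * pi * (2 * k + n - 1) / (2 * n))
  # pre-warped band edges for the bilinear transform
  fs <- sampling_rate
  w1 <- 2 * fs * tan(pi * low / fs)
  w2 <- 2 * fs * tan(pi * high / fs)
  bw <- w2 - w1
  wo <- sqrt(w1 * w2)
  # low-pass -> band-pass in zpk form: n zeros at s = 0, 2n poles
  ps <- p * bw / 2
  pbp <- c(ps + sqrt(ps^2 - wo^2), ps - sqrt(ps^2 - wo^2))
  # bilinear transform; zeros map to z = 1 (n-fold) and z = -1 (n-fold)
  fs2 <- 2 * fs
  pd <- (fs2 + pbp) / (fs2 - pbp)
  gain <- bw^n * Re(fs2^n / prod(fs2 - pbp))
  # pair poles with their conjugates into biquads, b = (1, 0, -1) each
  used <- rep(FALSE, length(pd))
  sos <- list()
  for (i in seq_along(pd)) {
    if (used[i]) next
    used[i] <- TRUE
    rem <- which(!used)
    j <- rem[which.min(abs(pd[rem] - Conj(pd[i])))]
    used[j] <- TRUE
    a <- Re(c(1, -(pd[i] + pd[j]), pd[i] * pd[j]))
    sos[[length(sos) + 1L]] <- list(b = c(1, 0, -1), a = a)
  }
  sos[[1]]$b <- sos[[1]]$b * gain
  # steady-state (unit-step) internal state per section, scaled by the
  # first sample at application time to suppress start-up transients
  for (s in seq_along(sos)) {
    b <- sos[[s]]$b; a <- sos[[s]]$a
    y0 <- sum(b) / sum(a)
    sos[[s]]$zi <- c(y0 - b[1], b[3] - a[3] * y0)
  }
  structure(list(sos = sos, band = c(low, high), order = n,
                 sampling_rate = fs),
            class = "bci_bandpass")
}

#' @export
print.bci_bandpass <- function(x, ...) {
  cat(sprintf("<bci_bandpass> order-%d Butterworth (%g, %g) Hz @ %g Hz, %d sections\n",
              x$order, x$band[1], x$band[2], x$sampling_rate, length(x$sos)))
  invisible(x)
}

#' Single-pass magnitude response of a designed filter
#'
#' @param bf a [design_bandpass()] object.
#' @param freq_hz frequencies at which to evaluate `|H(f)|`.
#' @return numeric vector of single-pass gains. Forward-backward application
#'   realizes the squared magnitude.
#' @export
filter_gain <- function(bf, freq_hz) {
  vapply(freq_hz, function(f) {
    w <- exp(-1i * 2 * pi * f / bf$sampling_rate)
    h <- 1 + 0i
    for (s in bf$sos)
      h <- h * (sum(s$b * w^(0:2)) / sum(s$a * w^(0:2)))
    Mod(h)
  }, numeric(1))
}

# one causal pass of the section cascade over the columns of X
# (samples x series), with steady-state initial conditions
sosfilt_mat <- function(sos, X) {
  n <- nrow(X)
  for (s in sos) {
    b <- s$b; a <- s$a
    Y <- X
    z1 <- s$zi[1] * X[1, ]
    z2 <- s$zi[2] * X[1, ]
    for (t in seq_len(n)) {
      xt <- X[t, ]
      yt <- b[1] * xt + z1
      z1 <- b[2] * xt - a[2] * yt + z2
      z2 <- b[3] * xt - a[3] * yt
      Y[t, ] <- yt
    }
    X <- Y
  }
  X
}

# zero-phase (forward-backward) filtering of matrix columns with
# odd-symmetric edge extension; pad is truncated for short signals
filtfilt_mat <- function(bf, X, pad = NULL) {
  n <- nrow(X)
  if (is.null(pad)) pad <- 3L * (2L * bf$order + 1L)
  pad <- min(pad, n - 1L)
  if (pad < 1L) stop("signal too short to filter")
  ext <- rbind(2 * X[rep(1L, pad), , drop = FALSE] - X[(pad + 1L):2L, , drop = FALSE],
               X,
               2 * X[rep(n, pad), , drop = FALSE] - X[(n - 1L):(n - pad), , drop = FALSE])
  Y <- sosfilt_mat(bf$sos, ext)
  Y <- sosfilt_mat(bf$sos, Y[nrow(Y):1L, , drop = FALSE])
  Y <- Y[nrow(Y):1L, , drop = FALSE]
  Y[(pad + 1L):(pad + n), , drop = FALSE]
}

#' Apply a filter bank, producing one filtered copy per band
#'
#' Filtering is zero-phase: each block is applied forward and backward, so
#' the effective attenuation is the squared single-pass magnitude and no
#' group delay is introduced. Edges are handled by odd-symmetric extension
#' (pad length `3 * (2 * order + 1)`, truncated for short signals) with
#' steady-state initial conditions.
#'
#' @param x a [epoch_set()] or [recording()].
#' @param bank a [filter_bank()].
#' @return a named list with one filtered copy of `x` per band, in band
#'   order; names are `"low-high"` in Hz.
#' @export
apply_filterbank <- function(x, bank) UseMethod("apply_filterbank")

#' @export
apply_filterbank.bci_epochs <- function(x, bank) {
  stopifnot(inherits(bank, "bci_filterbank"))
  len <- epoch_length(x)
  if (len < 3L * bank$order + 1L)
    stop("epochs of length ", len, " are shorter than the filter warm-up (",
         3L * bank$order + 1L, " samples)")
  d <- dim(x$epochs)
  # samples x (trial*channel) matrix view
  flat <- matrix(aperm(x$epochs, c(3, 2, 1)), nrow = d[3])
  out <- lapply(bank$bands, function(b) {
    bf <- design_bandpass(b, x$sampling_rate, bank$order)
    filt <- filtfilt_mat(bf, flat)
    y <- x
    y$epochs <- aperm(array(filt, dim = c(d[3], d[2], d[1])), c(3, 2, 1))
    y
  })
  names(out) <- vapply(bank$bands, function(b)
    sprintf("%g-%g", b[[1]], b[[2]]), character(1))
  out
}

#' @export
apply_filterbank.bci_recording <- function(x, bank) {
  stopifnot(inherits(bank, "bci_filterbank"))
  if (n_samples(x) < 3L * bank$order + 1L)
    stop("recording shorter than the filter warm-up")
  out <- lapply(bank$bands, function(b) {
    bf <- design_bandpass(b, x$sampling_rate, bank$order)
    y <- x
    y$signals <- t(filtfilt_mat(bf, t(x$signals)))
    rownames(y$signals) <- x$channel_labels
    y
  })
  names(out) <- vapply(bank$bands, function(b)
    sprintf("%g-%g", b[[1]], b[[2]]), character(1))
  out
}
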
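#' Normalized class covariance matrix
#'
#' For every trial of the requested class, computes the trial covariance
#' `C = X X' / trace(X X')` (channels x channels, trace one) and returns the
#' arithmetic mean over trials. Epochs are expected to be centered
#' ([center_epochs()]) so that `X X'` measures signal variance.
#'
#' @param ep a centered [epoch_set()].
#' @param label class whose trials enter the average.
#' @return symmetric positive semi-definite matrix with unit trace.
#' @export
class_covariance <- function(ep, label) {
  stopifnot(inherits(ep, "bci_epochs"))
  idx <- which(ep$labels == label)
  if (length(idx) < 2L)
    stop("need >= 2 trials of class '", label, "', found ", length(idx))
  nc <- n_channels(ep)
  acc <- matrix(0, nc, nc)
  for (i in idx) {
    X <- matrix(ep$epochs[i, , ], nrow = nc)
    C <- tcrossprod(X)
    tr <- sum(diag(C))
    if (tr <= 0)
      stop("degenerate (zero-signal) trial '", ep$trial_ids[i], "'")
    acc <- acc + C / tr
  }
  S <- acc / length(idx)
  (S + t(S)) / 2
}

#' Fit Common Spatial Patterns from a pair of class covariances
#'
#' Finds spatial filters `w` maximizing the variance ratio
#' `(w' S+ w) / (w' (S+ + S-) w)` by whitening the composite covariance
#' `S+ + S-` and eigendecomposing the whitened `S+` (the standard numerical
#' realization of simultaneous diagonalization). Each filter satisfies
#' `w (S+ + S-) w' = 1` and `w S+ w' = lambda`, with eigenvalues sorted in
#' descending order: the first filters maximize the positive class's share
#' of variance, the last ones minimize it.
#'
#' A ridge of `1e-10 * trace` is added to the composite before whitening to
#' tolerate the mild rank deficiency introduced by zero-phase narrow-band
#' filtering of short epochs. Filter signs are fixed so the
#' largest-magnitude coefficient of each filter is positive, and ties in
#' `lambda` keep their original eigen-order, so results are deterministic
#' across linear-algebra backends.
#'
#' @param sigma_pos,sigma_neg symmetric PSD covariance matrices of the
#'   positive and negative (or rest) class, same dimensions.
#' @param class_pair length-2 character, `(positive, negative)` labels.
#' @return object of class `bci_csp` with fields `W` (components x channels,
#'   rows ordered by descending eigenvalue), `eigenvalues` and `class_pair`.
#' @export
fit_csp <- function(sigma_pos, sigma_neg, class_pair = c("+", "-")) {
  if (!all(dim(sigma_pos) == dim(sigma_neg)))
    stop("covariance dimensions differ")
  if (max(abs(sigma_pos - t(sigma_pos))) > 1e-8 ||
      max(abs(sigma_neg - t(sigma_neg))) > 1e-8)
    stop("covariances must be symmetric")
  comp <- sigma_pos + sigma_neg
  nc <- nrow(comp)
  comp <- comp + diag(1e-10 * sum(diag(comp)), nc)
  ec <- eigen(comp, symmetric = TRUE)
  if (min(ec$values) <= 0)
    stop("composite covariance not positive definite (min eigenvalue ",
         format(min(ec$values)), ")")
  # whitening transform P: P comp P' = I
  P <- diag(1 / sqrt(ec$values), nc) %*% t(ec$vectors)
  S <- P %*% sigma_pos %*% t(P)
  S <- (S + t(S)) / 2
  es <- eigen(S, symmetric = TRUE)      # values descending, deterministic
  W <- t(es$vectors) %*% P              # rows are spatial filters
  lambda <- pmin(pmax(es$values, 0), 1)
  # sign convention: largest-magnitude coefficient positive
  for (i in seq_len(nrow(W))) {
    j <- which.max(abs(W[i, ]))
    if (W[i, j] < 0) W[i, ] <- -W[i, ]
  }
  structure(list(W = W, eigenvalues = lambda,
                 class_pair = as.character(class_pair)),
            class = "bci_csp")
}

#' @export
print.bci_csp <- function(x, ...) {
  cat(sprintf("<bci_csp> %d filters x %d channels ('%s' vs '%s')\n",
              nrow(x$W), ncol(x$W), x$class_pair[1], x$class_pair[2]))
  cat("  eigenvalues:", paste(sprintf("%.3f", x$eigenvalues), collapse = " "), "\n")
  invisible(x)
}

#' Retain the most discriminative CSP filter pairs
#'
#' Keeps the `n_pairs` filters with the largest eigenvalues and the
#' `n_pairs` with the smallest (symmetric top/bottom selection), preserving
#' descending-eigenvalue order.
#'
#' @param filters a [fit_csp()] result.
#' @param n_pairs number of pairs; `2 * n_pairs` must not exceed the
#'   component count.
#' @return a `bci_csp` with `2 * n_pairs` filters.
#' @export
select_filters <- function(filters, n_pairs) {
  stopifnot(inherits(filters, "bci_csp"))
  m <- nrow(filters$W)
  if (2L * n_pairs > m)
    stop("cannot select ", n_pairs, " pairs from ", m, " components")
  keep <- c(seq_len(n_pairs), (m - n_pairs + 1L):m)
  keep <- sort(unique(keep))
  filters$W <- filters$W[keep, , drop = FALSE]
  filters$eigenvalues <- filters$eigenvalues[keep]
  filters
}

#' Project epochs into CSP surrogate-channel space
#'
#' Each trial `X` is mapped to `W X`; labels and trial count are unchanged
#' and the surrogate channel count equals the number of retained filters.
#'
#' @param filters a [fit_csp()] result (possibly after [select_filters()]).
#' @param ep a [epoch_set()] with matching channel count.
#' @return epoch set in surrogate-channel space.
#' @export
apply_csp <- function(filters, ep) {
  stopifnot(inherits(filters, "bci_csp"), inherits(ep, "bci_epochs"))
  if (ncol(filters$W) != n_channels(ep))
    stop("filter expects ", ncol(filters$W), " channels, epochs have ",
         n_channels(ep))
  d <- dim(ep$epochs)
  m <- nrow(filters$W)
  out <- array(0, dim = c(d[1], m, d[3]))
  for (i in seq_len(d[1]))
    out[i, , ] <- filters$W %*% matrix(ep$epochs[i, , ], nrow = d[2])
  ep$epochs <- out
  ep$channel_labels <- sprintf("csp%02d", seq_len(m))
  ep
}

#' One-against-others multiclass CSP
#'
#' For each class (in sorted label order) fits CSP with that class as
#' positive and the trialwise pool of all other classes as negative.
#' Downstream feature extraction concatenates the per-class filter sets.
#'
#' @param ep a centered [epoch_set()] with >= 2 classes, each with >= 2
#'   trials.
#' @return named list of [fit_csp()] results, one per sorted class label.
#' @export
fit_csp_ovr <- function(ep) {
  stopifnot(inherits(ep, "bci_epochs"))
  classes <- sort(unique(ep$labels))
  if (length(classes) < 2L)
    stop("one-against-others CSP needs >= 2 classes, found ", length(classes))
  out <- lapply(classes, function(cl) {
    pos <- class_covariance(ep, cl)
    others <- subset_epochs(ep, ep$labels != cl)
    if (n_trials(others) < 2L)
      stop("fewer than 2 trials outside class '", cl, "'")
    others$labels <- rep("rest", n_trials(others))
    neg <- class_covariance(others, "rest")
    fit_csp(pos, neg, class_pair = c(cl, "rest"))
  })
  names(out) <- classes
  out
}
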
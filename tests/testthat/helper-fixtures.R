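# shared fixture builders; all randomness is locally seeded

# recording whose single channel holds its own 0-based sample index,
# making epoch sample arithmetic directly observable
index_recording <- function(n = 1000, fs = 100, markers = NULL) {
  if (is.null(markers)) markers <- markers_table(500L, "cue")
  recording(matrix(as.numeric(0:(n - 1)), nrow = 1), fs,
            channel_labels = "ch01", markers = markers, id = "idxrec")
}

random_epochs <- function(n_trials = 6, n_channels = 3, n_samples = 100,
                          labels = NULL, fs = 100, seed = 1) {
  set.seed(seed)
  if (is.null(labels)) labels <- rep(c("a", "b"), length.out = n_trials)
  epoch_set(array(rnorm(n_trials * n_channels * n_samples),
                  dim = c(n_trials, n_channels, n_samples)),
            labels = labels, sampling_rate = fs, window = c(0, n_samples / fs))
}

# random symmetric positive-definite matrix with unit trace
random_psd <- function(d, seed) {
  set.seed(seed)
  A <- matrix(rnorm(d * d), d)
  S <- crossprod(A) + diag(0.1, d)
  S / sum(diag(S))
}

# two well-separated Gaussian blobs in 2-d
blob_features <- function(n_per_class = 100, sep = 6, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per_class * 2), ncol = 2),
             matrix(rnorm(n_per_class * 2) + sep, ncol = 2))
  feature_matrix(X, c("f1", "f2"),
                 rep(c("a", "b"), each = n_per_class))
}

xor_features <- function(n = 400, seed = 2) {
  set.seed(seed)
  q <- sample(0:3, n, replace = TRUE)
  X <- cbind(ifelse(q %% 2 == 0, -1, 1), ifelse(q < 2, -1, 1)) +
    matrix(rnorm(2 * n, sd = 0.2), ncol = 2)
  feature_matrix(X, c("f1", "f2"),
                 ifelse(xor(q %% 2 == 1, q >= 2), "pos", "neg"))
}

# tiny synthetic subject for pipeline-level tests
small_synth_epochs <- function(trials_per_class = 15, seed = 5,
                               erd = 0.3, noise_sd = 5) {
  sc <- synth_config(trials_per_class = trials_per_class,
                     trial_length_s = 2,
                     modulation = rbind(left = c(1, erd, 1),
                                        right = c(erd, 1, 1)),
                     noise_sd = noise_sd, seed = seed)
  extract_epochs(generate_synchronous(sc), 0, 2)
}
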
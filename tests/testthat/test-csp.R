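test_that("class covariance is the mean of trace-normalized trial covariances", {
  # two identical trials X = [[1,-1],[1,-1]]: XX' = [[2,2],[2,2]], trace 4,
  # so the trace-normalized covariance is [[.5,.5],[.5,.5]] (trace one)
  arr <- array(0, dim = c(2, 2, 2))
  arr[1, , ] <- rbind(c(1, -1), c(1, -1))
  arr[2, , ] <- rbind(c(1, -1), c(1, -1))
  ep <- epoch_set(arr, c("a", "a"), 100)
  C <- class_covariance(ep, "a")
  expect_equal(C, matrix(0.5, 2, 2), tolerance = 1e-12)
  expect_equal(sum(diag(C)), 1)
})

test_that("white-noise covariance approaches I/N", {
  ep <- random_epochs(n_trials = 200, n_channels = 3, n_samples = 200,
                      labels = rep("w", 200), seed = 12)
  C <- class_covariance(center_epochs(ep), "w")
  expect_equal(diag(C), rep(1 / 3, 3), tolerance = 0.02)
  off <- C[upper.tri(C)]
  expect_true(all(abs(off) < 3 / sqrt(200 * 200)))  # ~3 SE of a mean correlation
})

test_that("degenerate inputs to class covariance error out", {
  ep <- random_epochs()
  expect_error(class_covariance(ep, "missing"), "trials of class")
  arr <- array(0, dim = c(2, 2, 10))
  zep <- epoch_set(arr, c("z", "z"), 100)
  expect_error(class_covariance(zep, "z"), "degenerate")
})

test_that("CSP solves the variance-ratio objective", {
  # identical covariances: every direction splits variance evenly
  S <- random_psd(3, seed = 1)
  f_eq <- fit_csp(S, S)
  expect_equal(f_eq$eigenvalues, rep(0.5, 3), tolerance = 1e-8)

  # already-diagonal pair: eigenvalues are the variance shares, axes filters
  f_diag <- fit_csp(diag(c(0.8, 0.2)), diag(c(0.2, 0.8)))
  expect_equal(f_diag$eigenvalues, c(0.8, 0.2), tolerance = 1e-8)
  expect_equal(abs(f_diag$W) > 0.5, rbind(c(TRUE, FALSE), c(FALSE, TRUE)))

  # whitening normalization: w (S+ + S-) w' = 1, w S+ w' = lambda
  Sp <- random_psd(4, seed = 2); Sn <- random_psd(4, seed = 3)
  f <- fit_csp(Sp, Sn)
  for (i in 1:4) {
    w <- f$W[i, , drop = FALSE]
    expect_equal(as.numeric(w %*% (Sp + Sn) %*% t(w)), 1, tolerance = 1e-6)
    expect_equal(as.numeric(w %*% Sp %*% t(w)), f$eigenvalues[i],
                 tolerance = 1e-6)
  }
})

test_that("extreme eigenvalues dominate the Rayleigh quotient", {
  Sp <- random_psd(4, seed = 21); Sn <- random_psd(4, seed = 22)
  f <- fit_csp(Sp, Sn)
  set.seed(23)
  W <- matrix(rnorm(4 * 10000), ncol = 4)
  q <- apply(W, 1, function(w) {
    a <- as.numeric(w %*% Sp %*% w)
    b <- as.numeric(w %*% Sn %*% w)
    a / (a + b)
  })
  expect_gte(max(f$eigenvalues), max(q) - 1e-9)
  expect_lte(min(f$eigenvalues), min(q) + 1e-9)
})

test_that("CSP respects label-swap, permutation and scale symmetries", {
  Sp <- random_psd(4, seed = 31); Sn <- random_psd(4, seed = 32)
  f <- fit_csp(Sp, Sn)
  # label swap: eigenvalues map to 1 - lambda, reversed order
  g <- fit_csp(Sn, Sp)
  expect_equal(g$eigenvalues, rev(1 - f$eigenvalues), tolerance = 1e-8)
  # channel permutation permutes filter columns, eigenvalues unchanged
  perm <- c(3, 1, 4, 2)
  fp <- fit_csp(Sp[perm, perm], Sn[perm, perm])
  expect_equal(fp$eigenvalues, f$eigenvalues, tolerance = 1e-8)
  expect_equal(abs(fp$W), abs(f$W[, perm]), tolerance = 1e-6)
  # global signal scaling leaves normalized covariances untouched upstream;
  # scaling both covariances equally leaves lambda and W direction unchanged
  fs2 <- fit_csp(Sp * 5, Sn * 5)
  expect_equal(fs2$eigenvalues, f$eigenvalues, tolerance = 1e-8)
})

test_that("filter selection keeps the symmetric extremes in order", {
  Sp <- random_psd(6, seed = 41); Sn <- random_psd(6, seed = 42)
  f <- fit_csp(Sp, Sn)
  s1 <- select_filters(f, 1)
  expect_equal(s1$eigenvalues, f$eigenvalues[c(1, 6)])
  s3 <- select_filters(f, 3)
  expect_equal(s3$eigenvalues, f$eigenvalues)
  expect_error(select_filters(f, 4), "cannot select")
})

test_that("projection produces surrogate channels with whitened variance", {
  ep <- center_epochs(small_synth_epochs(trials_per_class = 8, seed = 9))
  classes <- sort(unique(ep$labels))
  Sp <- class_covariance(ep, classes[1])
  Sn <- class_covariance(ep, classes[2])
  f <- fit_csp(Sp, Sn, classes)
  proj <- apply_csp(f, ep)
  expect_equal(n_channels(proj), nrow(f$W))
  expect_identical(proj$labels, ep$labels)
  # identity projection leaves epochs unchanged
  idf <- f; idf$W <- diag(n_channels(ep)); idf$eigenvalues <- rep(0.5, n_channels(ep))
  expect_equal(apply_csp(idf, ep)$epochs, ep$epochs, tolerance = 1e-12)
  # per-component class variances (trace-normalized, as in training) sum to 1
  per_class_var <- sapply(classes, function(cl) {
    idx <- which(ep$labels == cl)
    comp_var <- sapply(idx, function(i) {
      X <- matrix(ep$epochs[i, , ], nrow = n_channels(ep))
      tr <- sum(X^2)
      rowSums((f$W %*% X)^2) / tr
    })
    rowMeans(comp_var)
  })
  expect_equal(unname(rowSums(per_class_var)), rep(1, nrow(f$W)),
               tolerance = 1e-8)
  # dimension mismatch
  expect_error(apply_csp(f, random_epochs(n_channels = 4)), "channels")
})

test_that("one-against-others CSP mirrors for two classes and scales to four", {
  ep <- center_epochs(small_synth_epochs(trials_per_class = 8, seed = 10))
  ovr <- fit_csp_ovr(ep)
  expect_length(ovr, 2)
  expect_equal(ovr[[2]]$eigenvalues, rev(1 - ovr[[1]]$eigenvalues),
               tolerance = 1e-8)

  sc4 <- synth_config(classes = c("feet", "left", "right", "tongue"),
                      trials_per_class = 4, trial_length_s = 1,
                      modulation = matrix(runif(12, 0.3, 1.5), 4, 3),
                      seed = 3)
  ep4 <- center_epochs(extract_epochs(generate_synchronous(sc4), 0, 1))
  ovr4 <- fit_csp_ovr(ep4)
  expect_length(ovr4, 4)
  expect_named(ovr4, c("feet", "left", "right", "tongue"))

  ep1 <- subset_epochs(ep, ep$labels == ep$labels[1])
  expect_error(fit_csp_ovr(ep1), ">= 2 classes")
})
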
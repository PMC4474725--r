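#' Subjects-by-classifiers performance table
#'
#' Container for the scores (accuracy or AUC, higher is better) of `k`
#' classifiers evaluated on `N` subjects; the input of the rank-based
#' comparison layer.
#'
#' @param scores numeric matrix, subjects x classifiers, no missing cells.
#' @param subject_ids,classifier_ids row / column identifiers.
#' @param higher_is_better flag (default `TRUE`).
#' @return object of class `bci_performance`.
#' @export
performance_table <- function(scores, subject_ids = NULL,
                              classifier_ids = NULL,
                              higher_is_better = TRUE) {
  scores <- as.matrix(scores)
  if (anyNA(scores)) stop("performance table contains missing cells")
  if (ncol(scores) < 2L) stop("need >= 2 classifiers")
  if (nrow(scores) < 2L) stop("need >= 2 subjects")
  if (is.null(subject_ids)) subject_ids <- rownames(scores)
  if (is.null(subject_ids)) subject_ids <- sprintf("S%02d", seq_len(nrow(scores)))
  if (is.null(classifier_ids)) classifier_ids <- colnames(scores)
  if (is.null(classifier_ids)) classifier_ids <- sprintf("clf%d", seq_len(ncol(scores)))
  dimnames(scores) <- list(subject_ids, classifier_ids)
  structure(list(scores = scores, subject_ids = as.character(subject_ids),
                 classifier_ids = as.character(classifier_ids),
                 higher_is_better = isTRUE(higher_is_better)),
            class = "bci_performance")
}

#' @export
print.bci_performance <- function(x, ...) {
  cat(sprintf("<bci_performance> %d subjects x %d classifiers\n",
              nrow(x$scores), ncol(x$scores)))
  print(utils::head(x$scores, 4))
  if (nrow(x$scores) > 4) cat("...\n")
  invisible(x)
}

#' Per-subject ranks and average ranks
#'
#' Ranks the classifiers within each subject (rank 1 = best score; tied
#' scores receive the mean of the positions they span) and averages the
#' ranks over subjects. Each subject's ranks sum to `k(k+1)/2` regardless
#' of ties.
#'
#' @param perf a [performance_table()].
#' @return object of class `bci_ranks` with fields `ranks` (subjects x
#'   classifiers), `average_ranks`, `N` and `k`.
#' @export
rank_table <- function(perf) {
  stopifnot(inherits(perf, "bci_performance"))
  s <- perf$scores
  if (!perf$higher_is_better) s <- -s
  ranks <- t(apply(-s, 1, rank, ties.method = "average"))
  dimnames(ranks) <- dimnames(perf$scores)
  structure(list(ranks = ranks, average_ranks = colMeans(ranks),
                 N = nrow(ranks), k = ncol(ranks)),
            class = "bci_ranks")
}

#' @export
print.bci_ranks <- function(x, ...) {
  cat(sprintf("<bci_ranks> N=%d subjects, k=%d classifiers\n", x$N, x$k))
  avg <- sort(x$average_ranks)
  cat("  average ranks:",
      paste(sprintf("%s=%.4g", names(avg), avg), collapse = ", "), "\n")
  invisible(x)
}

#' Friedman rank test
#'
#' Classic Friedman chi-square statistic on a rank table:
#' `chi2 = 12N / (k(k+1)) * (sum_j R_j^2 - k(k+1)^2 / 4)` with `k - 1`
#' degrees of freedom, where `R_j` are the average ranks. The null
#' hypothesis is that all classifiers perform alike, so rank differences
#' are random. No tie correction is applied (ties are already mean-ranked).
#'
#' @param ranks a [rank_table()] result.
#' @return object of class `bci_friedman` with `chi2`, `df`, `p_value`.
#' @export
friedman_rank_test <- function(ranks) {
  stopifnot(inherits(ranks, "bci_ranks"))
  N <- ranks$N; k <- ranks$k
  if (N < 2L || k < 2L) stop("Friedman test needs N >= 2 and k >= 2")
  R <- ranks$average_ranks
  chi2 <- 12 * N / (k * (k + 1)) * (sum(R^2) - k * (k + 1)^2 / 4)
  chi2 <- max(chi2, 0)
  structure(list(chi2 = chi2, df = k - 1L,
                 p_value = stats::pchisq(chi2, k - 1L, lower.tail = FALSE)),
            class = "bci_friedman")
}

#' @export
print.bci_friedman <- function(x, ...) {
  cat(sprintf("Friedman chi2 = %.4g, df = %d, p = %.3g\n",
              x$chi2, x$df, x$p_value))
  invisible(x)
}

#' Holm step-down post-hoc comparison against the control classifier
#'
#' The classifier with the best (lowest) average rank is the control; every
#' other classifier `j` is compared to it with the normal statistic
#' `z = (R_j - R_control) / sqrt(k(k+1) / (6N))` and a raw two-sided
#' p-value. Comparisons are sorted by ascending p and rejected sequentially
#' while `p_(i) < alpha / (k - i)`; rejection stops at the first
#' non-rejection.
#'
#' @param ranks a [rank_table()] result.
#' @param alpha family-wise significance level (default 0.1).
#' @return object of class `bci_holm` with fields `control`, `alpha` and
#'   `comparisons` (data.frame: `classifier`, `z`, `p_value`, `threshold`,
#'   `rejected`, sorted by ascending p).
#' @export
holm_posthoc <- function(ranks, alpha = 0.1) {
  stopifnot(inherits(ranks, "bci_ranks"))
  N <- ranks$N; k <- ranks$k
  if (k < 2L) stop("post-hoc comparison needs k >= 2")
  R <- ranks$average_ranks
  control <- names(R)[which.min(R)]
  others <- setdiff(names(R), control)
  se <- sqrt(k * (k + 1) / (6 * N))
  z <- (R[others] - R[control]) / se
  p <- 2 * stats::pnorm(-abs(z))
  ord <- order(p)
  cmp <- data.frame(classifier = others[ord], z = unname(z[ord]),
                    p_value = unname(p[ord]),
                    threshold = alpha / (k - seq_along(ord)),
                    stringsAsFactors = FALSE)
  rejected <- logical(nrow(cmp))
  for (i in seq_len(nrow(cmp))) {
    if (cmp$p_value[i] < cmp$threshold[i]) rejected[i] <- TRUE else break
  }
  cmp$rejected <- rejected
  structure(list(control = control, alpha = alpha, comparisons = cmp,
                 N = N, k = k),
            class = "bci_holm")
}

#' @export
print.bci_holm <- function(x, ...) {
  cat(sprintf("Holm post-hoc vs control '%s' (alpha = %g)\n",
              x$control, x$alpha))
  df <- x$comparisons
  df$p_value <- sprintf("%.4f", truncate_decimals(df$p_value, 4))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Partition classifiers into recommended / not recommended
#'
#' The recommended set contains the control classifier plus every
#' classifier the Holm procedure could not show to be worse; rejected
#' classifiers are not recommended.
#'
#' @param holm a [holm_posthoc()] result.
#' @return list with character vectors `recommended` and
#'   `not_recommended`.
#' @export
recommended_set <- function(holm) {
  stopifnot(inherits(holm, "bci_holm"))
  cmp <- holm$comparisons
  list(recommended = c(holm$control, cmp$classifier[!cmp$rejected]),
       not_recommended = cmp$classifier[cmp$rejected])
}

#' Truncate values to a fixed number of decimals
#'
#' Truncation (toward zero), not rounding: reporting layers use it so that
#' e.g. an average rank of 1.8125 prints as 1.81 and a p-value of 0.004570
#' as 0.0045. The analysis functions themselves always return full
#' precision.
#'
#' @param x numeric vector.
#' @param digits decimals kept.
#' @return truncated values.
#' @export
truncate_decimals <- function(x, digits) {
  trunc(x * 10^digits) / 10^digits
}

#' Full rank-based comparison report
#'
#' Runs [rank_table()], [friedman_rank_test()], [holm_posthoc()] and
#' [recommended_set()] on a performance table and bundles the results.
#' The Holm step is reported regardless of the Friedman outcome; callers
#' following the classic protocol should consult `friedman$p_value` before
#' interpreting it.
#'
#' @param perf a [performance_table()].
#' @param alpha family-wise level for the Holm procedure.
#' @return object of class `bci_comparison`.
#' @export
compare_classifiers <- function(perf, alpha = 0.1) {
  ranks <- rank_table(perf)
  fr <- friedman_rank_test(ranks)
  holm <- holm_posthoc(ranks, alpha)
  rec <- recommended_set(holm)
  structure(list(ranks = ranks, friedman = fr, holm = holm,
                 recommended = rec$recommended,
                 not_recommended = rec$not_recommended, alpha = alpha),
            class = "bci_comparison")
}

#' @export
print.bci_comparison <- function(x, ...) {
  avg <- sort(x$ranks$average_ranks)
  cat("Average ranks (1 = best):\n")
  cat(" ", paste(sprintf("%s(%.2f)", names(avg), truncate_decimals(avg, 2)),
                 collapse = "  "), "\n")
  print(x$friedman)
  print(x$holm)
  cat("Recommended:", paste(sort(x$recommended), collapse = ", "), "\n")
  if (length(x$not_recommended))
    cat("Not recommended:", paste(sort(x$not_recommended), collapse = ", "), "\n")
  invisible(x)
}

#' Serialize a comparison report to JSON
#'
#' @param cmp a [compare_classifiers()] result.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_comparison_json <- function(cmp, path) {
  stopifnot(inherits(cmp, "bci_comparison"))
  holm <- cmp$holm$comparisons
  out <- list(
    average_ranks = as.list(cmp$ranks$average_ranks),
    friedman = list(chi2 = cmp$friedman$chi2, df = cmp$friedman$df,
                    p = cmp$friedman$p_value),
    holm = lapply(seq_len(nrow(holm)), function(i) list(
      pair = sprintf("%s vs. %s", holm$classifier[i], cmp$holm$control),
      z = holm$z[i], p = holm$p_value[i],
      threshold = holm$threshold[i], rejected = holm$rejected[i])),
    control = cmp$holm$control,
    alpha = cmp$alpha,
    recommended = cmp$recommended,
    not_recommended = cmp$not_recommended)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
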
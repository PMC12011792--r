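#' Paired t-test between two sets of fold-wise accuracies
#'
#' Two-sided paired t-test with the sample-SD (n-1) convention:
#' `t = mean(d) / (sd(d) / sqrt(n))` on the differences `d = a - b`, with
#' `n - 1` degrees of freedom. Antisymmetric in its arguments.
#'
#' @param a,b Equal-length numeric vectors (paired measurements), n >= 2.
#' @param alpha Significance level for the rejection flag (0.05).
#' @return A `t_test_result`: `t_statistic`, `df`, `p_value`, `reject_h0`.
#' @export
paired_t_test <- function(a, b, alpha = 0.05) {
  if (length(a) != length(b)) stop("length mismatch")
  n <- length(a)
  if (n < 2) stop("need at least 2 pairs")
  d <- a - b
  s <- stats::sd(d)
  if (s == 0) stop("degenerate pairing: zero-variance differences")
  t_stat <- mean(d) / (s / sqrt(n))
  p <- 2 * stats::pt(-abs(t_stat), df = n - 1)
  structure(list(t_statistic = t_stat, df = n - 1L, p_value = p,
                 reject_h0 = p < alpha, alpha = alpha),
            class = "t_test_result")
}

#' t-based confidence interval for a mean
#'
#' `mean +/- t_{n-1, 1-alpha/2} * sd / sqrt(n)` with the sample SD.
#'
#' @param values Numeric vector, n >= 2.
#' @param level Confidence level (0.95).
#' @return A `ci_result`: `mean`, `lower`, `upper`, `level`.
#' @export
mean_ci <- function(values, level = 0.95) {
  n <- length(values)
  if (n < 2) stop("need at least 2 values")
  m <- mean(values)
  half <- stats::qt(1 - (1 - level) / 2, df = n - 1) *
    stats::sd(values) / sqrt(n)
  structure(list(mean = m, lower = m - half, upper = m + half,
                 level = level),
            class = "ci_result")
}

#' Pairwise model comparison table
#'
#' Runs [paired_t_test()] on every pair of named fold-accuracy vectors and
#' formats the result like a model-comparison table (t statistic, p value,
#' significance at `alpha`).
#'
#' @param accuracy_sets Named list of equal-length numeric vectors.
#' @param alpha Significance level.
#' @return data.frame with one row per comparison.
#' @export
compare_models <- function(accuracy_sets, alpha = 0.05) {
  nms <- names(accuracy_sets)
  if (is.null(nms) || length(nms) < 2) stop("need >= 2 named accuracy sets")
  rows <- list()
  for (i in seq_along(nms)) for (j in seq_along(nms)) {
    if (j <= i) next
    tt <- paired_t_test(accuracy_sets[[i]], accuracy_sets[[j]],
                        alpha = alpha)
    rows[[length(rows) + 1]] <- data.frame(
      comparison = paste(nms[i], "vs.", nms[j]),
      t_statistic = tt$t_statistic, p_value = tt$p_value,
      significant = tt$reject_h0, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' @export
print.t_test_result <- function(x, ...) {
  cat(sprintf("<paired t-test: t=%.4f df=%d p=%.4f -> %s H0 at alpha=%g>\n",
              x$t_statistic, x$df, x$p_value,
              if (x$reject_h0) "reject" else "retain", x$alpha))
  invisible(x)
}

#' @export
print.ci_result <- function(x, ...) {
  cat(sprintf("<%.0f%% CI: mean=%.4f [%.4f, %.4f]>\n", 100 * x$level,
              x$mean, x$lower, x$upper))
  invisible(x)
}
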
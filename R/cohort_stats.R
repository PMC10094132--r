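#' Intraclass correlation for method reproducibility
#'
#' Two-way random-effects, absolute-agreement, single-measures intraclass
#' correlation (ICC(A,1)) computed from the two-way ANOVA mean squares of a
#' subjects x raters matrix of repeated quantifications:
#' `(MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`. The 95% confidence
#' interval uses the standard F-based interval (McGraw-Wong). The number of
#' raters is taken as the number of replicate experiments supplied.
#'
#' @param m Numeric matrix, subjects in rows, replicate
#'   experiments/raters in columns, no missing cells.
#' @param conf_level Confidence level (default 0.95).
#' @return Object of class `icc_result`: `estimate`, `ci_low`, `ci_high`,
#'   `n_subjects`, `n_raters`, `model_label`.
#' @export
icc_absolute_agreement <- function(m, conf_level = 0.95) {
  m <- as.matrix(m)
  n <- nrow(m); k <- ncol(m)
  if (n < 2 || k < 2 || anyNA(m))
    stop_dq("ICC needs >= 2 subjects, >= 2 raters and no missing cells",
            class = "dq_parameter_error")
  if (diff(range(m)) == 0)
    stop_dq("ICC undefined for a constant matrix", class = "dq_degenerate_error")
  grand <- mean(m)
  rm_ <- rowMeans(m); cm_ <- colMeans(m)
  msr <- k * sum((rm_ - grand)^2) / (n - 1)
  msc <- n * sum((cm_ - grand)^2) / (k - 1)
  sse <- sum((m - outer(rm_, rep(1, k)) - outer(rep(1, n), cm_) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))

  denom <- msr + (k - 1) * mse + k * (msc - mse) / n
  est <- if (denom <= 0) 0 else (msr - mse) / denom
  est <- min(1, max(-1, est))

  alpha <- 1 - conf_level
  if (mse <= 0 && msc <= 0) {
    ci <- c(est, est)                 # perfect replication: degenerate interval
  } else {
    a <- k * est / (n * (1 - est)); b <- 1 + k * est * (n - 1) / (n * (1 - est))
    if (!is.finite(a) || !is.finite(b)) {
      ci <- c(est, est)
    } else {
      v <- (a * msc + b * mse)^2 /
        ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
      fl <- stats::qf(1 - alpha / 2, n - 1, v)
      fu <- stats::qf(1 - alpha / 2, v, n - 1)
      lower <- n * (msr - fl * mse) /
        (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
      upper <- n * (fu * msr - mse) /
        (k * msc + (k * n - k - n) * mse + n * fu * msr)
      ci <- c(max(-1, lower), min(1, upper))
    }
  }
  structure(list(estimate = est, ci_low = ci[1], ci_high = ci[2],
                 n_subjects = n, n_raters = k, conf_level = conf_level,
                 model_label = "two-way random, absolute agreement, single measures (ICC(A,1))"),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC = %.3f, %d%% CI (%.2f, %.2f); %d subjects x %d raters\n  %s\n",
              x$estimate, round(100 * x$conf_level), x$ci_low, x$ci_high,
              x$n_subjects, x$n_raters, x$model_label))
  invisible(x)
}

#' Shapiro-Wilk normality test
#'
#' Thin wrapper returning the Shapiro-Wilk p-value, with the test's sample
#' size limits made explicit and constant input reported as a degenerate
#' error rather than an opaque failure.
#'
#' @param values Numeric vector, `3 <= n <= 5000`.
#' @return The p-value.
#' @export
normality_test <- function(values) {
  n <- length(values)
  if (n < 3 || n > 5000)
    stop_dq("Shapiro-Wilk requires 3 <= n <= 5000 (got ", n, ")",
            class = "dq_parameter_error")
  if (diff(range(values)) == 0)
    stop_dq("normality test undefined for constant input",
            class = "dq_degenerate_error")
  stats::shapiro.test(values)$p.value
}

#' Nonparametric group comparison of raw ROI intensities
#'
#' Kruskal-Wallis omnibus test across all groups plus two-sided unpaired
#' Wilcoxon rank-sum tests for every group pair, on raw (unpaired)
#' fluorescence values. Raw p-values are reported by default; `adjust =
#' "holm"` applies a Holm correction to the pairwise family.
#'
#' @param values_by_group Named list mapping group label to a numeric vector
#'   of ROI peak intensities (>= 2 groups, each n >= 3).
#' @param adjust `"none"` (default) or any [stats::p.adjust()] method for
#'   the pairwise p-values.
#' @return Object of class `group_comparison`: `omnibus_stat`, `omnibus_p`,
#'   `pairwise` (data frame), `group_summaries` (mean, SE, n per group).
#' @export
compare_groups <- function(values_by_group, adjust = "none") {
  if (!is.list(values_by_group) || length(values_by_group) < 2 ||
      is.null(names(values_by_group)))
    stop_dq("values_by_group must be a named list of >= 2 groups",
            class = "dq_parameter_error")
  ns <- vapply(values_by_group, length, integer(1))
  if (any(ns < 3))
    stop_dq("every group needs n >= 3", class = "dq_parameter_error")
  labels <- names(values_by_group)
  values_by_group <- values_by_group[sort(labels)]  # order-invariant output
  labels <- names(values_by_group)
  kw <- stats::kruskal.test(values_by_group)
  pairs <- utils::combn(labels, 2)
  pw <- data.frame(group_a = pairs[1, ], group_b = pairs[2, ],
                   statistic = NA_real_, p = NA_real_)
  for (i in seq_len(ncol(pairs))) {
    wt <- suppressWarnings(stats::wilcox.test(values_by_group[[pairs[1, i]]],
                                              values_by_group[[pairs[2, i]]],
                                              exact = FALSE))
    pw$statistic[i] <- unname(wt$statistic)
    pw$p[i] <- wt$p.value
  }
  if (adjust != "none") pw$p_adjusted <- stats::p.adjust(pw$p, adjust)
  gs <- data.frame(group = labels,
                   n = unname(ns[labels]),
                   mean = vapply(values_by_group, mean, numeric(1)),
                   se = vapply(values_by_group, function(v)
                     stats::sd(v) / sqrt(length(v)), numeric(1)))
  rownames(gs) <- NULL
  structure(list(omnibus_stat = unname(kw$statistic),
                 omnibus_p = kw$p.value, pairwise = pw,
                 group_summaries = gs, adjust = adjust),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis H = %.3f, p = %.3g across %d groups\n",
              x$omnibus_stat, x$omnibus_p, nrow(x$group_summaries)))
  for (i in seq_len(nrow(x$pairwise)))
    cat(sprintf("  %s vs %s: W = %.1f, p = %.3g\n", x$pairwise$group_a[i],
                x$pairwise$group_b[i], x$pairwise$statistic[i], x$pairwise$p[i]))
  invisible(x)
}

#' Manual vs automatic method comparison
#'
#' Two-sample Student t-test assuming equal variances (pooled variance,
#' two-sided) on per-biopsy mean intensities obtained with the two
#' methodologies.
#'
#' @param manual,auto Numeric vectors of per-biopsy means (each n >= 2).
#' @return Object of class `method_comparison`: `t_stat`, `p`, `n_manual`,
#'   `n_auto`, `mean_difference`.
#' @export
compare_methods <- function(manual, auto) {
  if (length(manual) < 2 || length(auto) < 2)
    stop_dq("both methods need n >= 2 biopsies", class = "dq_parameter_error")
  if (stats::var(manual) + stats::var(auto) == 0)
    stop_dq("zero pooled variance: t-test degenerate",
            class = "dq_degenerate_error")
  tt <- stats::t.test(manual, auto, var.equal = TRUE)
  structure(list(t_stat = unname(tt$statistic), p = tt$p.value,
                 n_manual = length(manual), n_auto = length(auto),
                 mean_difference = mean(manual) - mean(auto)),
            class = "method_comparison")
}

#' @export
print.method_comparison <- function(x, ...) {
  cat(sprintf("manual vs automatic: t = %.3f, p = %.3g (n = %d vs %d, mean diff %.1f a.u.)\n",
              x$t_stat, x$p, x$n_manual, x$n_auto, x$mean_difference))
  invisible(x)
}
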
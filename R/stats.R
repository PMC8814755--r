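# Cohort-level statistics: pooled-variance t tests, Tukey-Kramer all-pairs
# range tests, Bonferroni correction, notched-median summaries and post hoc
# power analysis based on the noncentral t distribution.

# exact power of the two-sided two-sample t test at standardized effect d
power_two_sample_t <- function(d, n_a, n_b, alpha) {
  df <- n_a + n_b - 2
  ncp <- abs(d) * sqrt(n_a * n_b / (n_a + n_b))
  crit <- stats::qt(1 - alpha / 2, df)
  1 - stats::pt(crit, df, ncp = ncp) + stats::pt(-crit, df, ncp = ncp)
}

#' Post hoc power of a two-sample t test
#'
#' Computes the power of the two-sided pooled-variance t test at the observed
#' standardized effect size (Cohen's d) and sample sizes, using the noncentral
#' t distribution exactly, together with the minimum effect size that would
#' reach a power of 0.80 at those sample sizes (found by bracketed
#' root-finding on the monotone forward power function).
#'
#' @param effect_size Standardized effect size d.
#' @param n_a,n_b Group sizes (>= 2).
#' @param alpha Significance criterion (two-sided).
#' @return List with `power` and `min_effect_for_power80`.
#' @export
posthoc_power <- function(effect_size, n_a, n_b, alpha = 0.05) {
  stopifnot(n_a >= 2, n_b >= 2, alpha > 0, alpha < 1)
  pw <- power_two_sample_t(effect_size, n_a, n_b, alpha)
  root <- stats::uniroot(function(d) power_two_sample_t(d, n_a, n_b, alpha) - 0.80,
                         interval = c(1e-8, 20), tol = 1e-9)$root
  list(power = pw, min_effect_for_power80 = root)
}

comparison_row <- function(group_a, group_b, metric, statistic, p, adjusted,
                           alpha, d, n_a, n_b, power = NA_real_,
                           min_eff = NA_real_, degenerate = FALSE) {
  data.frame(group_a = group_a, group_b = group_b, metric = metric,
             statistic = statistic, p_value = p, adjusted = adjusted,
             alpha = alpha, significant = is.finite(p) && p < alpha,
             effect_size = d, n_a = n_a, n_b = n_b, power = power,
             min_effect_for_power80 = min_eff, degenerate = degenerate,
             stringsAsFactors = FALSE)
}

#' Two-sample pooled-variance (Student) t test with power diagnostics
#'
#' Two-sided pooled-variance t test, Cohen's d effect size
#' `(mean_a - mean_b) / pooled sd`, and post hoc power at the observed effect.
#' A Welch test is available behind `var_equal = FALSE`. With zero pooled
#' variance the comparison degenerates: equal means give `p = 1`, unequal
#' means are flagged `degenerate` with `p = 0`.
#'
#' @param a,b Numeric vectors (n >= 2 each).
#' @param alpha Significance criterion.
#' @param var_equal Pool variances (Student) rather than Welch.
#' @param m_tests Number of planned tests; when > 1 a Bonferroni correction
#'   divides `alpha` for the significance call.
#' @param metric Optional metric label carried into the result.
#' @param group_a,group_b Optional group labels.
#' @param power Compute power diagnostics (disable for large simulations).
#' @return One-row data.frame (see fields of [tukey_all_pairs()] results).
#' @export
compare_two <- function(a, b, alpha = 0.05, var_equal = TRUE, m_tests = 1L,
                        metric = NA_character_, group_a = "a", group_b = "b",
                        power = TRUE) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  n_a <- length(a); n_b <- length(b)
  if (n_a < 2 || n_b < 2)
    stop("each group needs at least 2 finite values", call. = FALSE)
  adj <- if (m_tests > 1L) "bonferroni" else "none"
  alpha_eff <- alpha / max(1L, m_tests)
  diff <- mean(a) - mean(b)
  va <- stats::var(a); vb <- stats::var(b)
  s2p <- ((n_a - 1) * va + (n_b - 1) * vb) / (n_a + n_b - 2)
  if (s2p == 0) {
    if (diff == 0)
      return(comparison_row(group_a, group_b, metric, 0, 1, adj, alpha_eff,
                            0, n_a, n_b))
    return(comparison_row(group_a, group_b, metric, sign(diff) * Inf, 0, adj,
                          alpha_eff, sign(diff) * Inf, n_a, n_b,
                          degenerate = TRUE))
  }
  if (var_equal) {
    se <- sqrt(s2p * (1 / n_a + 1 / n_b))
    df <- n_a + n_b - 2
  } else {
    se <- sqrt(va / n_a + vb / n_b)
    df <- (va / n_a + vb / n_b)^2 /
      ((va / n_a)^2 / (n_a - 1) + (vb / n_b)^2 / (n_b - 1))
  }
  tstat <- diff / se
  p <- 2 * stats::pt(-abs(tstat), df)
  d <- diff / sqrt(s2p)
  pw <- me <- NA_real_
  if (power) {
    pp <- posthoc_power(d, n_a, n_b, alpha_eff)
    pw <- pp$power; me <- pp$min_effect_for_power80
  }
  comparison_row(group_a, group_b, metric, tstat, p, adj, alpha_eff, d,
                 n_a, n_b, pw, me)
}

as_group_list <- function(data, metric = NULL) {
  if (is.list(data) && !is.data.frame(data)) return(data)
  stopifnot(is.data.frame(data))
  df <- data
  if (!is.null(metric) && "metric" %in% names(df))
    df <- df[df$metric == metric, , drop = FALSE]
  split(df$value, df$group)
}

#' Tukey-Kramer all-pairs comparisons
#'
#' Simultaneous pairwise comparisons of three or more group means using the
#' studentized range distribution with the Tukey-Kramer unequal-n standard
#' error, controlling the family-wise error rate at `alpha`. With exactly two
#' groups the comparison delegates to [compare_two()].
#'
#' @param data Either a named list of numeric vectors, or a long data.frame
#'   with columns `group`, `value` (and optionally `metric`).
#' @param metric Optional metric name to filter a long data.frame and label
#'   the results.
#' @param alpha Family-wise significance criterion.
#' @param power Compute per-pair post hoc power diagnostics (pairwise t basis).
#' @return Data.frame with one row per pair: `group_a`, `group_b`, `metric`,
#'   `statistic` (studentized range q, or t for two groups), `p_value`,
#'   `adjusted`, `alpha`, `significant`, `effect_size` (Cohen's d on the
#'   pooled within-group sd), `n_a`, `n_b`, `power`,
#'   `min_effect_for_power80`, `degenerate`.
#' @export
tukey_all_pairs <- function(data, metric = NULL, alpha = 0.05, power = TRUE) {
  groups <- as_group_list(data, metric)
  groups <- lapply(groups, function(v) v[is.finite(v)])
  k <- length(groups)
  if (k < 2) stop("need at least two groups", call. = FALSE)
  ns <- vapply(groups, length, integer(1))
  if (any(ns < 2)) stop("every group needs at least 2 values", call. = FALSE)
  if (k == 2L) {
    return(compare_two(groups[[1]], groups[[2]], alpha = alpha,
                       metric = metric %||% NA_character_,
                       group_a = names(groups)[1], group_b = names(groups)[2],
                       power = power))
  }
  means <- vapply(groups, mean, numeric(1))
  vars <- vapply(groups, stats::var, numeric(1))
  df_err <- sum(ns) - k
  mse <- sum((ns - 1) * vars) / df_err
  pairs <- utils::combn(k, 2)
  rows <- vector("list", ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    diff <- means[i1] - means[i2]
    if (mse == 0) {
      rows[[j]] <- comparison_row(names(groups)[i1], names(groups)[i2],
                                  metric %||% NA_character_,
                                  if (diff == 0) 0 else sign(diff) * Inf,
                                  if (diff == 0) 1 else 0, "tukey", alpha,
                                  if (diff == 0) 0 else sign(diff) * Inf,
                                  ns[i1], ns[i2], degenerate = diff != 0)
      next
    }
    se <- sqrt(mse / 2 * (1 / ns[i1] + 1 / ns[i2]))
    q <- abs(diff) / se
    p <- stats::ptukey(q, nmeans = k, df = df_err, lower.tail = FALSE)
    d <- diff / sqrt(mse)
    pw <- me <- NA_real_
    if (power) {
      pp <- posthoc_power(d, ns[i1], ns[i2], alpha)
      pw <- pp$power; me <- pp$min_effect_for_power80
    }
    rows[[j]] <- comparison_row(names(groups)[i1], names(groups)[i2],
                                metric %||% NA_character_, sign(diff) * q, p,
                                "tukey", alpha, d, ns[i1], ns[i2], pw, me)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Notched box-plot summary of a metric vector
#'
#' Median and quartiles (linear-interpolation quantiles), with the notch
#' `median +/- 1.57 * IQR / sqrt(n)` — the McGill convention for an
#' approximate 95% confidence interval of the true median.
#'
#' @param values Numeric vector (n >= 2).
#' @return A list of class `mnps_box_summary`: `median`, `q1`, `q3`,
#'   `notch_low`, `notch_high`, `n`.
#' @export
notched_summary <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 2) stop("need at least 2 finite values", call. = FALSE)
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  half <- 1.57 * (q[3] - q[1]) / sqrt(n)
  structure(list(median = q[2], q1 = q[1], q3 = q[3],
                 notch_low = q[2] - half, notch_high = q[2] + half, n = n),
            class = "mnps_box_summary")
}

#' @export
print.mnps_box_summary <- function(x, ...) {
  cat(sprintf("median %.4g [notch %.4g, %.4g], IQR %.4g-%.4g, n = %d\n",
              x$median, x$notch_low, x$notch_high, x$q1, x$q3, x$n))
  invisible(x)
}
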
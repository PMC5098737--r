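# Group-comparison and correlation statistics.

new_group_comparison <- function(metric, group_a, group_b,
                                 mean_a, sd_a, n_a, mean_b, sd_b, n_b,
                                 t_stat, df, p_raw, welch = FALSE,
                                 degenerate = FALSE, alpha = 0.05) {
  structure(list(metric = metric, group_a = group_a, group_b = group_b,
                 mean_a = mean_a, sd_a = sd_a, n_a = n_a,
                 mean_b = mean_b, sd_b = sd_b, n_b = n_b,
                 t_stat = t_stat, df = df, p_raw = p_raw,
                 p_adjusted = p_raw, m = 1L,
                 significant = is.finite(p_raw) && p_raw < alpha,
                 welch = welch, degenerate = degenerate, alpha = alpha),
            class = "group_comparison")
}

#' Unpaired two-tailed t-test from summary statistics
#'
#' Two-sample t-test computed from group means, SDs and sizes — the form
#' needed to check published group summaries. Default is the classical
#' pooled (equal-variance) test; `welch = TRUE` uses the
#' Welch-Satterthwaite form. Zero variance in both groups with equal means
#' is returned as a degenerate comparison with `t = 0`, `p = 1`.
#'
#' @param mean_a,sd_a,n_a,mean_b,sd_b,n_b Group summaries (`n >= 2`).
#' @param metric,group_a,group_b Labels carried into the result.
#' @param welch Use the unequal-variance (Welch) form?
#' @param alpha Significance level for the `significant` flag.
#' @return Object of class `group_comparison` with `t_stat`, `df`, `p_raw`,
#'   `p_adjusted` (initially `p_raw`) and a `significant` flag.
#' @examples
#' ttest_summary(1.29, 0.12, 5, 0.63, 0.08, 5)$p_raw  # ~7e-6
#' @export
ttest_summary <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b,
                          metric = "metric", group_a = "A", group_b = "B",
                          welch = FALSE, alpha = 0.05) {
  assert_that(n_a >= 2 && n_b >= 2, "ttest: both groups need n >= 2")
  assert_that(sd_a >= 0 && sd_b >= 0, "ttest: SDs must be non-negative")
  if (sd_a == 0 && sd_b == 0) {
    if (mean_a == mean_b) {
      return(new_group_comparison(metric, group_a, group_b, mean_a, sd_a, n_a,
                                  mean_b, sd_b, n_b, t_stat = 0,
                                  df = n_a + n_b - 2, p_raw = 1,
                                  welch = welch, degenerate = TRUE, alpha = alpha))
    }
    return(new_group_comparison(metric, group_a, group_b, mean_a, sd_a, n_a,
                                mean_b, sd_b, n_b, t_stat = Inf,
                                df = n_a + n_b - 2, p_raw = 0,
                                welch = welch, degenerate = TRUE, alpha = alpha))
  }
  if (welch) {
    va <- sd_a^2 / n_a; vb <- sd_b^2 / n_b
    se <- sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (n_a - 1) + vb^2 / (n_b - 1))
  } else {
    sp2 <- ((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / (n_a + n_b - 2)
    se <- sqrt(sp2 * (1 / n_a + 1 / n_b))
    df <- n_a + n_b - 2
  }
  t_stat <- (mean_a - mean_b) / se
  p <- 2 * pt(-abs(t_stat), df)
  new_group_comparison(metric, group_a, group_b, mean_a, sd_a, n_a,
                       mean_b, sd_b, n_b, t_stat, df, p,
                       welch = welch, alpha = alpha)
}

#' Unpaired two-tailed t-test between two cohort groups
#'
#' Raw-sample path of [ttest_summary()]: extracts the metric for the two
#' named groups from a cohort table and compares them; the two paths agree
#' to machine precision on the same data.
#'
#' @param cohort Cohort `data.frame` (see [simulate_cohort()]).
#' @param metric Column name to compare.
#' @param group_a,group_b Group labels.
#' @param welch,alpha See [ttest_summary()].
#' @return A `group_comparison`.
#' @export
ttest_groups <- function(cohort, metric, group_a, group_b,
                         welch = FALSE, alpha = 0.05) {
  assert_that(metric %in% names(cohort),
              sprintf("ttest_groups: no column '%s' in cohort", metric))
  xa <- cohort[[metric]][cohort$group == group_a]
  xb <- cohort[[metric]][cohort$group == group_b]
  xa <- xa[is.finite(xa)]; xb <- xb[is.finite(xb)]
  assert_that(length(xa) >= 2 && length(xb) >= 2,
              "ttest_groups: both groups need n >= 2 complete observations")
  ttest_summary(mean(xa), sd0(xa), length(xa), mean(xb), sd0(xb), length(xb),
                metric = metric, group_a = group_a, group_b = group_b,
                welch = welch, alpha = alpha)
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: %s (%.4g±%.3g, n=%d) vs %s (%.4g±%.3g, n=%d)\n",
              x$metric, x$group_a, x$mean_a, x$sd_a, x$n_a,
              x$group_b, x$mean_b, x$sd_b, x$n_b))
  cat(sprintf("  t = %.3f, df = %.3g, p = %.3g (adjusted %.3g, m = %d)%s%s\n",
              x$t_stat, x$df, x$p_raw, x$p_adjusted, x$m,
              if (x$significant) " *" else "",
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Kolmogorov-Smirnov (Lilliefors) normality screen
#'
#' One-sample KS test against a normal distribution with mean and SD
#' estimated from the sample (Lilliefors correction). Uses the standard
#' Lilliefors p-value approximation for `n >= 4`; for `n = 3` the p-value
#' comes from a small fixed-seed Monte-Carlo null table. A constant sample
#' fails with a note. Failing metrics are reported but do not block t-tests.
#'
#' @param values Numeric sample, `n >= 3`.
#' @param alpha Significance level of the pass/fail flag.
#' @return List: `statistic` (D), `p`, `normal` (logical pass at `alpha`),
#'   `note`.
#' @export
ks_normality <- function(values, alpha = 0.05) {
  values <- values[is.finite(values)]
  n <- length(values)
  assert_that(n >= 3, "ks_normality: need at least 3 observations")
  if (sd0(values) == 0) {
    return(list(statistic = NA_real_, p = NA_real_, normal = FALSE,
                note = "constant sample: normality rejected by convention"))
  }
  if (n >= 4) {
    kt <- nortest::lillie.test(values)
    return(list(statistic = unname(kt$statistic), p = kt$p.value,
                normal = kt$p.value >= alpha, note = ""))
  }
  # n == 3: Lilliefors D with Monte-Carlo null distribution
  d_stat <- function(x) {
    z <- sort((x - mean(x)) / stats::sd(x))
    p <- pnorm(z)
    max(pmax(seq_len(3) / 3 - p, p - (seq_len(3) - 1) / 3))
  }
  d <- d_stat(values)
  null_d <- with_seed(20231107, replicate(4000, d_stat(rnorm(3))))
  p <- mean(null_d >= d)
  list(statistic = d, p = p, normal = p >= alpha, note = "Monte-Carlo p (n = 3)")
}

#' Correlate two cohort variables (Pearson or Spearman)
#'
#' `method = "auto"` selects Spearman's rank correlation when either
#' variable is an ordinal histology score (intimal arteritis, interstitial
#' inflammation, tubulitis, periarteritis) and Pearson's product-moment
#' correlation otherwise (MR metrics, F4/80 %). Ties are handled by
#' midranks; Spearman p-values are exact for n < 10 without ties and use
#' the t-approximation otherwise.
#'
#' @param cohort Cohort `data.frame`.
#' @param var_x,var_y Column names.
#' @param method `"auto"`, `"pearson"` or `"spearman"`.
#' @return Object of class `correlation_result`: `var_x`, `var_y`,
#'   `method`, `r`, `p`, `n`, `note`.
#' @export
correlate <- function(cohort, var_x, var_y, method = c("auto", "pearson", "spearman")) {
  method <- match.arg(method)
  for (v in c(var_x, var_y)) {
    assert_that(v %in% names(cohort), sprintf("correlate: no column '%s'", v))
  }
  x <- cohort[[var_x]]; y <- cohort[[var_y]]
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  assert_that(n >= 3, "correlate: need at least 3 paired complete observations")
  if (method == "auto") {
    ordinal <- c(var_x, var_y) %in% .cohort_scores
    method <- if (any(ordinal)) "spearman" else "pearson"
  }
  note <- ""
  if (sd0(x) == 0 || sd0(y) == 0) {
    return(structure(list(var_x = var_x, var_y = var_y, method = method,
                          r = NA_real_, p = NA_real_, n = n,
                          note = "constant variable: correlation undefined"),
                     class = "correlation_result"))
  }
  ct <- suppressWarnings(cor.test(x, y, method = method))
  structure(list(var_x = var_x, var_y = var_y, method = method,
                 r = unname(ct$estimate), p = ct$p.value, n = n, note = note),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("%s vs %s: %s r = %.3f (p = %.3g, n = %d)%s\n",
              x$var_x, x$var_y, x$method, x$r, x$p, x$n,
              if (nzchar(x$note)) paste0(" [", x$note, "]") else ""))
  invisible(x)
}

#' Bonferroni correction across a family of comparisons
#'
#' Sets `p_adjusted = min(1, m * p_raw)` on each comparison and re-evaluates
#' significance at its alpha. `m` defaults to the number of comparisons
#' supplied but may be set to the size of a larger test family.
#'
#' @param comparisons A `group_comparison`, or a list of them.
#' @param m Number of tests in the family (default: `length(comparisons)`).
#' @return The adjusted list (or single comparison, matching the input).
#' @export
bonferroni <- function(comparisons, m = NULL) {
  single <- inherits(comparisons, "group_comparison")
  if (single) comparisons <- list(comparisons)
  assert_that(all(vapply(comparisons, inherits, logical(1), "group_comparison")),
              "bonferroni: expected group_comparison objects")
  m <- as.integer(m %||% length(comparisons))
  assert_that(m >= 1L, "bonferroni: m must be >= 1")
  out <- lapply(comparisons, function(cmp) {
    cmp$p_adjusted <- min(1, m * cmp$p_raw)
    cmp$m <- m
    cmp$significant <- is.finite(cmp$p_adjusted) && cmp$p_adjusted < cmp$alpha
    cmp
  })
  if (single) out[[1]] else out
}

#' Tabulate group comparisons
#'
#' @param comparisons List of `group_comparison` objects.
#' @return A `data.frame`, one row per comparison.
#' @export
comparison_table <- function(comparisons) {
  if (inherits(comparisons, "group_comparison")) comparisons <- list(comparisons)
  do.call(rbind, lapply(comparisons, function(x) {
    data.frame(metric = x$metric, group_a = x$group_a, group_b = x$group_b,
               mean_a = x$mean_a, sd_a = x$sd_a, n_a = x$n_a,
               mean_b = x$mean_b, sd_b = x$sd_b, n_b = x$n_b,
               t_stat = x$t_stat, df = x$df, p_raw = x$p_raw,
               p_adjusted = x$p_adjusted, significant = x$significant,
               stringsAsFactors = FALSE)
  }))
}
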
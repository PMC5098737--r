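test_that("pooled t-test on published-style summaries matches the closed form", {
  cmp <- ttest_summary(1.29, 0.12, 5, 0.63, 0.08, 5)
  # closed-form pooled t on the printed summaries
  sp <- sqrt((4 * 0.12^2 + 4 * 0.08^2) / 8)
  t_oracle <- (1.29 - 0.63) / (sp * sqrt(2 / 5))
  expect_equal(cmp$t_stat, t_oracle, tolerance = 1e-12)
  expect_equal(cmp$t_stat, 10.23, tolerance = 1e-3)
  expect_equal(cmp$df, 8)
  expect_lt(cmp$p_raw, 0.001)
})

test_that("summary and raw-sample t-test paths agree to machine precision and match stats::t.test", {
  set.seed(10)
  co <- data.frame(group = rep(c("A", "B"), each = 8),
                   adc = c(rnorm(8, 1.2, 0.1), rnorm(8, 0.8, 0.15)))
  raw <- ttest_groups(co, "adc", "A", "B")
  xa <- co$adc[co$group == "A"]; xb <- co$adc[co$group == "B"]
  smry <- ttest_summary(mean(xa), sd(xa), 8, mean(xb), sd(xb), 8)
  expect_equal(raw$t_stat, smry$t_stat, tolerance = 1e-14)
  expect_equal(raw$p_raw, smry$p_raw, tolerance = 1e-14)
  tt <- t.test(xa, xb, var.equal = TRUE)
  expect_equal(raw$t_stat, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(raw$p_raw, tt$p.value, tolerance = 1e-12)
  # Welch variant against its stats::t.test counterpart
  tw <- t.test(xa, xb)
  w <- ttest_groups(co, "adc", "A", "B", welch = TRUE)
  expect_equal(w$t_stat, unname(tw$statistic), tolerance = 1e-12)
  expect_equal(w$df, unname(tw$parameter), tolerance = 1e-12)
  expect_equal(w$p_raw, tw$p.value, tolerance = 1e-12)
})

test_that("identical samples give t = 0, p = 1; zero-variance cases are flagged degenerate", {
  co <- data.frame(group = rep(c("A", "B"), each = 4), m = rep(c(1, 2, 3, 4), 2))
  cmp <- ttest_groups(co, "m", "A", "B")
  expect_equal(cmp$t_stat, 0)
  expect_equal(cmp$p_raw, 1)
  deg <- ttest_summary(2, 0, 5, 2, 0, 5)
  expect_true(deg$degenerate)
  expect_equal(deg$p_raw, 1)
})

test_that("Lilliefors normality screen calibrates on normal and non-normal samples", {
  set.seed(3)
  expect_true(ks_normality(rnorm(1000))$normal)
  two_point <- rep(c(0, 1), 500)
  expect_false(ks_normality(two_point)$normal)
  expect_error(ks_normality(c(1, 2)), "at least 3")
  const <- ks_normality(rep(5, 10))
  expect_false(const$normal)
  expect_match(const$note, "constant")
  n3 <- ks_normality(c(0.1, 0.5, 2.0))
  expect_true(is.finite(n3$p))
})

test_that("correlation: exact linear, exact rank, and automatic method selection", {
  x <- 1:10
  co <- data.frame(adc = x, f480_pct = 2 * x + 1,
                   interstitial_inflammation = rep(0:1, 5))
  r <- correlate(co, "adc", "f480_pct")
  expect_equal(r$method, "pearson")  # both metric variables
  expect_equal(r$r, 1)

  co3 <- data.frame(a = c(1, 2, 3), b = c(3, 1, 2))
  rs <- correlate(co3, "a", "b", method = "spearman")
  expect_equal(rs$r, -0.5)  # rank-permutation brute force: 1 - 6*6/24

  auto <- correlate(co, "adc", "interstitial_inflammation")
  expect_equal(auto$method, "spearman")  # ordinal histology triggers rank method

  const <- correlate(data.frame(a = 1:5, b = rep(2, 5)), "a", "b", method = "pearson")
  expect_true(is.na(const$r))
  expect_match(const$note, "constant")
})

test_that("Spearman correlation is invariant under monotone transforms", {
  set.seed(8)
  co <- data.frame(x = rnorm(40), y = rnorm(40))
  r0 <- correlate(co, "x", "y", method = "spearman")$r
  co$x <- exp(3 * co$x)          # strictly increasing transform
  co$y <- co$y^3                 # strictly increasing transform
  expect_equal(correlate(co, "x", "y", method = "spearman")$r, r0, tolerance = 1e-12)
})

test_that("Bonferroni adjustment follows min(1, m p), never decreases p, matches p.adjust", {
  mk <- function(p) {
    c <- ttest_summary(1, 0.1, 5, 1.2, 0.1, 5)
    c$p_raw <- p; c$p_adjusted <- p
    c
  }
  adj <- bonferroni(lapply(c(0.01, 0.4, 7e-6), mk), m = 4)
  expect_equal(vapply(adj, `[[`, numeric(1), "p_adjusted"),
               c(0.04, 1.0, 2.8e-5))
  expect_true(adj[[1]]$significant)
  expect_false(adj[[2]]$significant)
  # p_raw = 7e-6, m = 10 stays far below 0.001
  expect_lt(bonferroni(mk(7e-6), m = 10)$p_adjusted, 0.001)
  # identity at m = 1; equivalence with p.adjust when m equals the family size
  expect_equal(bonferroni(mk(0.03), m = 1)$p_adjusted, 0.03)
  ps <- c(0.001, 0.02, 0.7)
  adj2 <- bonferroni(lapply(ps, mk))
  expect_equal(vapply(adj2, `[[`, numeric(1), "p_adjusted"),
               p.adjust(ps, method = "bonferroni"))
  expect_true(all(vapply(adj2, `[[`, numeric(1), "p_adjusted") >= ps))
})
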
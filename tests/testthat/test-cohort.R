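test_that("default cohort reproduces the five-group, 25-animal study layout", {
  co <- simulate_cohort(seed = 1)
  expect_equal(nrow(co), 25)
  expect_equal(names(co), c("animal_id", "group", "adc", "plasma_flow",
                            "intimal_arteritis", "interstitial_inflammation",
                            "tubulitis", "periarteritis", "f480_pct"))
  expect_equal(sort(unique(co$group)),
               sort(c("syngeneic", "revmNOX-E36", "CsA", "mNOX-E36", "CsA+mNOX-E36")))
  expect_equal(unname(table(co$group)), rep(5L, 5), ignore_attr = TRUE)
  expect_false(any(duplicated(co$animal_id)))
  scores <- c("intimal_arteritis", "interstitial_inflammation", "tubulitis", "periarteritis")
  for (v in scores) {
    expect_true(all(co[[v]] %in% 0:3))  # per-animal scores are integers 0-3
  }
  expect_true(all(co$f480_pct >= 0) && all(co$adc >= 0) && all(co$plasma_flow >= 0))
})

test_that("identical seeds reproduce the cohort; empty group lists error", {
  expect_identical(simulate_cohort(seed = 7), simulate_cohort(seed = 7))
  expect_false(identical(simulate_cohort(seed = 7), simulate_cohort(seed = 8)))
  expect_error(cohort_model(list()), "empty")
  expect_error(cohort_model(coupling = c(adc_f480 = -2)), "\\[-1, 1\\]")
})

test_that("zero coupling gives independent variables at large n", {
  # couplings are pooled correlations: with a single group there is no
  # between-group component, so zero coupling means independence
  g <- default_groups(n = 6000)[2]
  m <- cohort_model(g, coupling = c(adc_f480 = 0, adc_interstitial = 0,
                                    pf_arteritis = 0))
  co <- simulate_cohort(m, seed = 12)
  expect_lt(abs(cor(co$adc, co$f480_pct)), 0.05)
  expect_lt(abs(cor(co$plasma_flow, co$intimal_arteritis)), 0.05)
  expect_lt(abs(cor(co$adc, co$interstitial_inflammation)), 0.05)
})

test_that("group marginal means converge to the specification at n = 1e5", {
  m <- cohort_model(default_groups(n = 1e5))
  co <- simulate_cohort(m, seed = 31)
  for (g in m$groups) {
    sub <- co[co$group == g$name, ]
    for (v in c("adc", "plasma_flow", "f480_pct")) {
      expect_lt(abs(mean(sub[[v]]) - g$means[[v]]) / g$means[[v]], 0.01,
                label = sprintf("%s mean of %s", v, g$name))
    }
    for (v in c("intimal_arteritis", "interstitial_inflammation",
                "tubulitis", "periarteritis")) {
      # ordinal means: absolute tolerance (several targets are near zero)
      expect_lt(abs(mean(sub[[v]]) - g$means[[v]]), 0.02,
                label = sprintf("%s mean of %s", v, g$name))
    }
    for (v in c("adc", "plasma_flow", "f480_pct")) {
      expect_lt(abs(sd(sub[[v]]) - g$sds[[v]]) / g$sds[[v]], 0.05,
                label = sprintf("%s sd of %s", v, g$name))
    }
  }
})

test_that("empirical pooled correlations match the calibrated attainable values", {
  m <- cohort_model(default_groups(n = 2e4))
  co <- simulate_cohort(m, seed = 55)
  emp <- c(cor(co$adc, co$f480_pct),
           cor(co$adc, co$interstitial_inflammation),
           cor(co$plasma_flow, co$intimal_arteritis))
  cal <- vapply(m$pairs, `[[`, numeric(1), "attained")
  expect_equal(unname(emp), unname(cal), tolerance = 0.02)
})

test_that("native reference group is available but excluded by default", {
  g6 <- default_groups(include_native = TRUE)
  expect_equal(length(g6), 6L)
  co <- simulate_cohort(g6, seed = 2)
  expect_equal(nrow(co), 30)
  expect_true("native" %in% co$group)
})

test_that("replicated simulation tags cohorts and keeps the per-replicate layout", {
  co <- simulate_cohort(cohort_model(), seed = 9, replicates = 4)
  expect_equal(nrow(co), 100)
  expect_equal(names(co)[1], "replicate")
  expect_equal(unname(table(co$replicate)), rep(25L, 4), ignore_attr = TRUE)
})
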
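std_b <- make_protocol()$b_values

test_that("perfusion fraction is the normalized intercept deficit (fp = (M0-Mint)/M0)", {
  # Dp so large that the perfusion pool is invisible above b = 0:
  # the high-b intercept is exactly M0 (1 - fp)
  sig <- ivim_sig <- 100 * (0.2 * exp(-std_b * 1) + 0.8 * exp(-std_b * 1e-3))
  fit <- fit_ivim_segmented(voxel_series(sig))
  expect_equal(fit$m0[1, 1, 1], 100)
  expect_equal(fit$m_int[1, 1, 1], 80, tolerance = 1e-6)
  expect_equal(fit$fp[1, 1, 1], 0.2, tolerance = 1e-7)
})

test_that("pure monoexponential voxels degenerate to fp = 0 with exact Dt", {
  sig <- 1000 * exp(-std_b * 1.0e-3)
  fit <- fit_ivim_segmented(voxel_series(sig))
  expect_equal(fit$dt[1, 1, 1], 1.0e-3, tolerance = 1e-6)
  expect_lt(abs(fit$fp[1, 1, 1]), 1e-9)
  expect_false(fit$dp_valid[1, 1, 1])  # no perfusion pool to fit
})

test_that("standard perfused voxel is recovered within the verified tolerances", {
  sig <- 1000 * (0.2 * exp(-std_b * 10e-3) + 0.8 * exp(-std_b * 1.0e-3))
  fit <- fit_ivim_segmented(voxel_series(sig))
  # residual pseudo-diffusion contamination at b = 400 bounds the bias
  expect_lt(abs(fit$dt[1, 1, 1] - 1.0e-3) / 1.0e-3, 0.02)
  expect_lt(abs(fit$fp[1, 1, 1] - 0.2), 0.015)
  expect_lt(abs(fit$dp[1, 1, 1] - 10e-3) / 10e-3, 0.10)
})

test_that("intercept identity m_int = m0 (1 - fp_raw) holds before clamping", {
  set.seed(99)
  for (i in 1:50) {
    fp <- runif(1, 0, 0.4); dp <- runif(1, 5e-3, 50e-3)
    dt <- runif(1, 0.4e-3, 2e-3); m0 <- runif(1, 200, 2000)
    sig <- m0 * (fp * exp(-std_b * dp) + (1 - fp) * exp(-std_b * dt))
    fit <- fit_ivim_segmented(voxel_series(sig))
    expect_equal(fit$m0[1, 1, 1] * (1 - fit$fp_raw[1, 1, 1]),
                 fit$m_int[1, 1, 1], tolerance = 1e-10)
  }
})

test_that("negative raw fp is clamped to 0 and dp marked invalid", {
  # b = 0 sample depressed below the high-b intercept
  sig <- 1000 * exp(-std_b * 1.0e-3)
  sig[1] <- 900
  fit <- fit_ivim_segmented(voxel_series(sig))
  expect_lt(fit$fp_raw[1, 1, 1], 0)
  expect_equal(fit$fp[1, 1, 1], 0)
  expect_false(fit$dp_valid[1, 1, 1])
  expect_equal(fit$dt[1, 1, 1], 1.0e-3, tolerance = 1e-6)  # dt retained
})

test_that("noisy recovery at SNR 50 matches the expected error widths", {
  p <- make_protocol(dwi_shape = c(32, 32, 1))
  shape <- p$dwi_shape
  ph <- make_phantom(p)
  ph$m0_map <- array(1000, dim = shape)
  ph$fp_map <- array(0.2, dim = shape)
  ph$dp_map <- array(10e-3, dim = shape)
  ph$dt_map <- array(1.0e-3, dim = shape)
  s <- simulate_dwi(ph, noise_sd = 1000 / 50, seed = 21)
  mask <- array(TRUE, dim = shape)
  fit <- fit_ivim_segmented(s, mask = mask)
  ok <- fit$valid
  expect_gt(sum(ok), 1000)
  # widths from first-order error propagation of the three-point high-b fit
  # (slope SD ~16% of Dt at SNR 50 => median ~11%); see the methods vignette
  rel <- function(est, truth) abs(est[ok] - truth) / truth
  expect_lt(median(rel(fit$dt, 1.0e-3)), 0.15)
  expect_lt(median(abs(fit$fp[ok] - 0.2) / 0.2), 0.30)
  dp_ok <- fit$dp_valid
  expect_lt(median(abs(fit$dp[dp_ok] - 10e-3) / 10e-3), 0.50)
  # clamping invariants under noise
  expect_true(all(fit$fp[ok] >= 0 & fit$fp[ok] <= 1))
  expect_true(all(fit$dt[ok] >= 0))
  expect_true(all(fit$dp[dp_ok] >= fit$dt[dp_ok]))
})

test_that("b-value preconditions are enforced", {
  sig <- 1000 * exp(-std_b * 1e-3)
  expect_error(fit_ivim_segmented(voxel_series(sig), b_threshold = 700),
               "at least 2 b-values above")
  p2 <- raw_protocol(c(10, 400, 600, 800))
  expect_error(fit_ivim_segmented(voxel_series(1000 * exp(-p2$b_values * 1e-3), p2)),
               "b = 0")
})
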
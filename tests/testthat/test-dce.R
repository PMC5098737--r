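small_p <- make_protocol(dwi_shape = c(12, 12, 1), dce_shape = c(12, 12, 1))

test_that("relative enhancement conversion is exact, scale-free and guards the baseline", {
  d <- array(100, dim = c(2, 2, 1, 20))
  s <- dce_series(d, 1.5, 5)
  conc <- signal_to_concentration(s)
  expect_true(all(conc$conc == 0))         # constant signal -> zero concentration

  d2 <- d; d2[1, 1, 1, 10] <- 150
  c2 <- signal_to_concentration(dce_series(d2, 1.5, 5))
  expect_equal(c2$conc[1, 1, 1, 10], 0.5)  # (150 - 100) / 100

  c3 <- signal_to_concentration(dce_series(2 * d2, 1.5, 5))
  expect_equal(c3$conc, c2$conc)           # doubling all signals cancels

  d4 <- d2; d4[2, 2, 1, ] <- 0
  c4 <- signal_to_concentration(dce_series(d4, 1.5, 5))
  expect_false(c4$valid[2, 2, 1])          # non-positive baseline -> invalid voxel
})

test_that("deconvolution against a unit-impulse AIF returns the tissue curve", {
  dt <- 1.5
  aif <- c(1 / dt, rep(0, 29))
  tis <- 0.01 * exp(-(0:29) * dt / 20)
  h <- deconvolve(tis, aif, dt, reg = 0)
  expect_equal(h$h, tis, tolerance = 1e-12)
})

test_that("zero tissue gives a zero response; zero AIF is singular", {
  aif <- aif_gamma_variate((0:59) * 1.5)
  h <- deconvolve(rep(0, 60), aif, 1.5, reg = 1e-6)
  expect_equal(max(abs(h$h)), 0, tolerance = 1e-12)
  expect_error(deconvolve(rep(0, 60), rep(0, 60), 1.5), "singular")
  expect_error(deconvolve(rep(0, 60), aif, 1.5, reg = 1), "reg")
  expect_error(deconvolve(rep(0, 10), aif, 1.5), "equal length")
})

test_that("impulse metrics: closed-form exponential response and direct formulas", {
  # fine grid so the discrete max/integral approach the continuous values
  t <- seq(0, 600, by = 0.01)
  h <- impulse_metrics(51.03 / 6000 * exp(-t * (51.03 / 6000) / 0.30),
                       frame_interval = 0.01)
  expect_equal(h$fp, 51.03, tolerance = 1e-9)
  expect_equal(h$ecv, 30, tolerance = 1e-3)
  expect_equal(h$mtt, 30 / 51.03, tolerance = 1e-3)  # ~0.588 min

  # single-frame response: direct formulas
  m <- impulse_metrics(c(0.01, 0, 0, 0), frame_interval = 1.5)
  expect_equal(m$fp, 0.01 * 6000)
  expect_equal(m$ecv, 0.01 * 1.5 * 100)

  # homogeneity: scaling h scales fp and ecv, leaves mtt fixed
  m2 <- impulse_metrics(c(0.02, 0, 0, 0), frame_interval = 1.5)
  expect_equal(m2$fp, 2 * m$fp)
  expect_equal(m2$ecv, 2 * m$ecv)
  expect_equal(m2$mtt, m$mtt)

  expect_false(impulse_metrics(c(-1, 0, 0), frame_interval = 1.5)$valid)
})

test_that("noiseless forward/inverse round trip recovers FP and ECV within 5%", {
  ph <- make_phantom(small_p, graft = list(fp_dce = 23.48, ecv = 30))
  dce <- simulate_dce(ph)
  fit <- fit_dce(dce, mask = ph$kidney_mask, aif_mask = ph$artery_mask, reg = 1e-6)
  expect_lt(abs(fit$result$fp - 23.48) / 23.48, 0.05)
  expect_lt(abs(fit$result$ecv - 30) / 30, 0.05)
  expect_equal(fit$result$mtt * fit$result$fp, fit$result$ecv, tolerance = 1e-12)
})

test_that("linearity: scaling the tissue curve scales fp and ecv, not mtt", {
  ph <- make_phantom(small_p, graft = list(fp_dce = 40, ecv = 25))
  dce <- simulate_dce(ph)
  conc <- signal_to_concentration(dce)
  vox <- which(ph$kidney_mask)[1]
  ijk <- arrayInd(vox, dim(ph$kidney_mask))
  tis <- conc$conc[ijk[1], ijk[2], ijk[3], ]
  m1 <- impulse_metrics(deconvolve(tis, dce$aif, 1.5, reg = 1e-6))
  m3 <- impulse_metrics(deconvolve(3 * tis, dce$aif, 1.5, reg = 1e-6))
  expect_equal(m3$fp, 3 * m1$fp, tolerance = 1e-8)
  expect_equal(m3$ecv, 3 * m1$ecv, tolerance = 1e-8)
  expect_equal(m3$mtt, m1$mtt, tolerance = 1e-8)
})

test_that("increasing TSVD truncation never increases the response peak (noiseless)", {
  ph <- make_phantom(small_p, graft = list(fp_dce = 51.03, ecv = 30))
  dce <- simulate_dce(ph)
  conc <- signal_to_concentration(dce)
  vox <- which(ph$kidney_mask)[1]
  ijk <- arrayInd(vox, dim(ph$kidney_mask))
  tis <- conc$conc[ijk[1], ijk[2], ijk[3], ]
  peaks <- vapply(c(1e-6, 0.01, 0.02, 0.05, 0.1, 0.15, 0.3), function(r) {
    max(deconvolve(tis, dce$aif, 1.5, reg = r)$h)
  }, numeric(1))
  expect_true(all(diff(peaks) <= 1e-12))
})

test_that("quasi-continuous data at 1.5 s sampling recover FP within 5%; ECV error grows with frame interval", {
  FP <- 51.03; ECV <- 30
  run <- function(dtc, reg) {
    os <- 30
    dtf <- dtc / os
    tf <- seq(0, 360, by = dtf)
    aif_f <- aif_gamma_variate(tf, t0 = 15)
    h_f <- FP / 6000 * exp(-tf * (FP / 6000) / (ECV / 100))
    cv <- convolve(aif_f, rev(h_f), type = "open")[seq_along(tf)] * dtf
    idx <- seq(1, length(tf), by = os)[seq_len(round(360 / dtc))]
    impulse_metrics(deconvolve(cv[idx], aif_f[idx], dtc, reg = reg))
  }
  # moderate truncation controls the front artifact of continuous data
  expect_lt(abs(run(1.5, 0.01)$fp - FP) / FP, 0.05)
  ecv_err <- vapply(c(0.5, 1.5, 3, 6), function(dtc) {
    abs(run(dtc, 1e-6)$ecv - ECV)
  }, numeric(1))
  expect_true(all(diff(ecv_err) > 0))  # integral degrades monotonically
})

test_that("noisy ROI analysis at SNR 20 is centered within 10% of truth", {
  ph <- make_phantom(small_p, graft = list(fp_dce = 51.03, ecv = 30))
  fps <- vapply(1:20, function(i) {
    d <- simulate_dce(ph, noise_sd = 100 / 20, seed = 400 + i)
    fit_dce(d, mask = ph$kidney_mask, aif_mask = ph$artery_mask, reg = 0.15)$result$fp
  }, numeric(1))
  expect_lt(abs(mean(fps) - 51.03) / 51.03, 0.10)
})

test_that("disjoint ROIs are analysed independently and voxel maps keep the MTT identity", {
  ph <- make_phantom(small_p, graft = list(fp_dce = 23.48, ecv = 30),
                     native = list(fp_dce = 46.65, ecv = 30))
  dce <- simulate_dce(ph)
  fg <- fit_dce(dce, mask = ph$kidney_mask, aif_mask = ph$artery_mask, reg = 1e-6)
  fn <- fit_dce(dce, mask = ph$native_mask, aif_mask = ph$artery_mask, reg = 1e-6)
  expect_lt(abs(fg$result$fp - 23.48) / 23.48, 0.05)
  expect_lt(abs(fn$result$fp - 46.65) / 46.65, 0.05)  # no cross-talk

  vx <- fit_dce(dce, mask = ph$kidney_mask, aif_mask = ph$artery_mask,
                reg = 1e-6, mode = "voxel")
  ok <- vx$maps$valid
  expect_true(all(abs(vx$maps$mtt[ok] * vx$maps$fp[ok] - vx$maps$ecv[ok]) < 1e-9))
  expect_equal(mean(vx$maps$fp[ok]), 23.48, tolerance = 0.05)
})

test_that("degenerate residue (ECV = 0 with FP > 0) is rejected; FP = 0 gives flat curves", {
  expect_error(simulate_dce(make_phantom(small_p, graft = list(fp_dce = 10, ecv = 0))),
               "degenerate residue")
  ph0 <- make_phantom(small_p, graft = list(fp_dce = 0, ecv = 0),
                      native = list(fp_dce = 0, ecv = 0))
  d0 <- simulate_dce(ph0)
  expect_true(all(d0$data[ph0$kidney_mask] == 100))  # baseline only, no inflow
})
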
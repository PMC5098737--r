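#' Construct a dynamic contrast-enhanced series
#'
#' @param data 4-D numeric array (x, y, slice, frame) of signal intensities.
#' @param frame_interval Temporal resolution in seconds.
#' @param baseline_frames Number of pre-contrast frames (>= 1, < total).
#' @param aif Optional known arterial concentration curve (simulation truth).
#' @param protocol Optional [make_protocol()] the series was generated under.
#' @return Object of class `dce_series`.
#' @export
dce_series <- function(data, frame_interval, baseline_frames,
                       aif = NULL, protocol = NULL) {
  assert_that(length(dim(data)) == 4L, "DCE data must be a 4-D array (x, y, slice, frame)")
  n_frames <- dim(data)[4]
  assert_that(n_frames >= 3L, "DCE series needs at least 3 frames")
  assert_that(frame_interval > 0, "frame_interval must be > 0")
  baseline_frames <- as.integer(baseline_frames)
  assert_that(baseline_frames >= 1L && baseline_frames < n_frames,
              "baseline_frames must be >= 1 and smaller than the frame count")
  structure(list(data = data, frame_interval = frame_interval,
                 baseline_frames = baseline_frames, aif = aif,
                 protocol = protocol),
            class = "dce_series")
}

#' Arterial input function: gamma-variate bolus with recirculation tail
#'
#' First-pass bolus modelled as a peak-normalized gamma variate
#' \eqn{((t-t_0)/t_p)^\alpha e^{\alpha(1 - (t-t_0)/t_p)}} plus a slower
#' washout tail \eqn{k (1 - e^{-(t-t_0)/t_p}) e^{-(t-t_0)/\tau}}; zero before
#' bolus arrival \eqn{t_0}. Units are concentration-proportional (peak 1).
#'
#' @param t Time points in seconds.
#' @param t0 Bolus arrival time (s).
#' @param alpha Gamma-variate shape (dimensionless).
#' @param tp Time to peak after arrival (s).
#' @param k Recirculation tail amplitude relative to the peak.
#' @param tau Tail washout time constant (s).
#' @return Numeric vector, non-negative, finite integral.
#' @export
aif_gamma_variate <- function(t, t0 = 15, alpha = 2.5, tp = 4.5,
                              k = 0.2, tau = 80) {
  assert_that(alpha > 0 && tp > 0 && tau > 0 && k >= 0,
              "AIF parameters must define a non-negative curve")
  dtu <- pmax(t - t0, 0)
  bolus <- (dtu / tp)^alpha * exp(alpha * (1 - dtu / tp))
  tail <- k * (1 - exp(-dtu / tp)) * exp(-dtu / tau)
  out <- bolus + tail
  out[t <= t0] <- 0
  out
}

# one-compartment residue-weighted impulse response, per-second units:
# h(t) = FP' * exp(-t * FP'/ECV'), FP' = fp/6000 (1/s), ECV' = ecv/100
impulse_response_1c <- function(t, fp, ecv) {
  fps <- fp / 6000
  ecvf <- ecv / 100
  if (ecvf <= 0) {
    if (fps > 0) stop_renalmr("degenerate residue: ECV = 0 with FP > 0")
    return(rep(0, length(t)))
  }
  fps * exp(-t * fps / ecvf)
}

# lower-triangular rectangle-rule convolution operator of a sampled curve
conv_matrix <- function(curve, dt) {
  n <- length(curve)
  A <- matrix(0, n, n)
  for (j in seq_len(n)) A[j:n, j] <- curve[seq_len(n - j + 1)]
  A * dt
}

#' Simulate a DCE series from a phantom (one-compartment bolus passage)
#'
#' The tissue concentration curve in each perfused voxel is the discrete
#' convolution of the arterial input function with the one-compartment
#' impulse response \eqn{h(t) = F_P e^{-t F_P / ECV}} (plasma flow expressed
#' per second internally), using the same lower-triangular rectangle-rule
#' operator that [deconvolve()] inverts, so that noiseless series satisfy the
#' convolution identity to numerical precision. Voxels in the phantom's
#' artery mask carry the AIF itself. Signal is a linear function of
#' concentration: `S = baseline_signal * (1 + c)`, so that relative
#' enhancement recovers `c` exactly. `noise_sd > 0` adds white Gaussian noise
#' in signal units.
#'
#' With `oversample > 1` the convolution runs on a grid refined by that
#' factor and is then point-sampled at the frame times — a quasi-continuous
#' generator used to study discretization error versus frame interval.
#'
#' @param phantom [make_phantom()] object providing `fp_dce_map`, `ecv_map`
#'   and `artery_mask`.
#' @param protocol Acquisition protocol; defaults to the phantom's.
#' @param aif_params Named list overriding [aif_gamma_variate()] parameters.
#' @param noise_sd Additive Gaussian noise SD in signal units.
#' @param seed Integer seed for reproducible noise.
#' @param baseline_frames Pre-contrast frames; also sets bolus arrival
#'   `t0 = baseline_frames * frame_interval` unless `aif_params$t0` is given.
#' @param baseline_signal Pre-contrast signal level (arbitrary units).
#' @param oversample Integer temporal refinement factor for the forward model.
#' @return A [dce_series()] carrying the true frame-grid AIF in `$aif`.
#' @export
simulate_dce <- function(phantom, protocol = phantom$protocol,
                         aif_params = list(), noise_sd = 0, seed = NULL,
                         baseline_frames = 10L, baseline_signal = 100,
                         oversample = 1L) {
  assert_that(noise_sd >= 0, "noise_sd must be >= 0")
  assert_that(all(dim(phantom$fp_dce_map) == protocol$dce_shape),
              "dimension error: phantom grid does not match protocol dce_shape")
  oversample <- as.integer(oversample)
  assert_that(oversample >= 1L, "oversample must be a positive integer")
  dt <- protocol$frame_interval
  nf <- protocol$n_frames
  t_frames <- (seq_len(nf) - 1) * dt
  aif_params$t0 <- aif_params$t0 %||% (baseline_frames * dt)

  fine_dt <- dt / oversample
  t_fine <- seq(0, t_frames[nf], by = fine_dt)
  aif_fine <- do.call(aif_gamma_variate, c(list(t = t_fine), aif_params))
  pick <- match(round(t_frames / fine_dt), round(t_fine / fine_dt))
  aif <- aif_fine[pick]

  if (any(phantom$ecv_map == 0 & phantom$fp_dce_map > 0)) {
    stop_renalmr("degenerate residue: ECV = 0 with FP > 0 in phantom")
  }

  A <- conv_matrix(aif_fine, fine_dt)
  shape <- dim(phantom$fp_dce_map)
  conc <- array(0, dim = c(shape, nf))
  # tissue parameters are piecewise constant: convolve once per unique pair
  key <- paste(phantom$fp_dce_map, phantom$ecv_map)
  for (k in unique(key[phantom$fp_dce_map > 0])) {
    vox <- which(key == k & phantom$fp_dce_map > 0)
    fp <- phantom$fp_dce_map[vox[1]]
    ecv <- phantom$ecv_map[vox[1]]
    h <- impulse_response_1c(t_fine, fp, ecv)
    curve <- drop(A %*% h)[pick]
    for (i in seq_len(nf)) conc[vox + (i - 1) * prod(shape)] <- curve[i]
  }
  if (any(phantom$artery_mask)) {
    vox <- which(phantom$artery_mask)
    for (i in seq_len(nf)) conc[vox + (i - 1) * prod(shape)] <- aif[i]
  }

  signal <- baseline_signal * (1 + conc)
  if (noise_sd > 0) {
    signal <- with_seed(seed, signal + array(rnorm(length(signal), sd = noise_sd),
                                             dim = dim(signal)))
  }
  dce_series(signal, dt, baseline_frames, aif = aif, protocol = protocol)
}
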
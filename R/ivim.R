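# Segmented biexponential IVIM analysis.

#' Segmented IVIM fit (perfusion fraction, pseudo- and tissue diffusivity)
#'
#' Three-step voxelwise estimation of the biexponential
#' intravoxel-incoherent-motion model
#' \eqn{M(b) = M_0 (f_p e^{-b D_p} + (1-f_p) e^{-b D_t})}:
#'
#' 1. **Tissue diffusivity.** For b-values where \eqn{b D_p \gg 1} the
#'    pseudo-diffusion compartment has decayed, leaving
#'    \eqn{M_{high}(b) = M_0 (1-f_p) e^{-b D_t}}; \eqn{D_t} and the zero
#'    intercept \eqn{M_{int} = M_0 (1-f_p)} come from a weighted log-linear
#'    fit of the points with `b > b_threshold` (strict).
#' 2. **Perfusion fraction.** \eqn{f_p = (M_0 - M_{int}) / M_0} with
#'    \eqn{M_0} the measured unweighted (b = 0) signal; clamped to `[0, 1]`.
#'    A negative raw value (intercept above the measured signal) yields
#'    `fp = 0` and an invalid `dp`.
#' 3. **Pseudo-diffusivity.** \eqn{D_p} from a bounded one-dimensional
#'    least-squares search of the full model over all b-values on
#'    `[dt, dp_max]`, with \eqn{D_t} and \eqn{f_p} held fixed.
#'
#' @param series A [dwi_series()].
#' @param b_threshold Asymptotic-range threshold in s/mm^2 (default 200;
#'   only `b > b_threshold` enters step 1).
#' @param mask Optional ROI; defaults to the series mask, else whole volume.
#' @param dp_max Upper search bound for `dp` in mm^2/s.
#' @return Object of class `ivim_fit`: 3-D arrays `m0`, `fp`, `dp`, `dt`,
#'   `m_int`, `fp_raw` (unclamped, for the `m_int = m0 (1 - fp)` identity)
#'   and logical `valid` (step-1 fit usable) and `dp_valid`.
#' @examples
#' ph <- make_phantom(make_protocol(dwi_shape = c(8, 8, 1)))
#' fit <- fit_ivim_segmented(simulate_dwi(ph))
#' @export
fit_ivim_segmented <- function(series, b_threshold = 200, mask = NULL,
                               dp_max = 0.5) {
  b <- series$protocol$b_values
  hi <- b > b_threshold
  if (sum(hi) < 2L) {
    stop_renalmr("fit_ivim_segmented: need at least 2 b-values above b_threshold")
  }
  if (!any(b == 0)) stop_renalmr("fit_ivim_segmented: need a measured b = 0 point")
  sm <- series_matrix(series, mask)

  ll <- loglinear_fit(sm$m[, hi, drop = FALSE], b[hi])
  dt_v <- pmax(-ll$slope, 0)
  m_int <- exp(ll$intercept)
  m0 <- sm$m[, which(b == 0)[1]]

  valid_v <- ll$n_used >= 2L & is.finite(ll$slope) & m0 > 0
  fp_raw <- ifelse(m0 > 0, (m0 - m_int) / m0, NA_real_)
  fp <- pmin(pmax(fp_raw, 0), 1)
  fp[!valid_v] <- NA_real_
  dt_v[!valid_v] <- NA_real_

  dp <- rep(NA_real_, length(m0))
  dp_valid <- rep(FALSE, length(m0))
  # a numerically-zero perfusion pool leaves dp unidentifiable
  fit_idx <- which(valid_v & fp_raw > 1e-6)
  for (i in fit_idx) {
    sse <- function(dpi) {
      sum((sm$m[i, ] - ivim_signal(b, m0[i], fp[i], dpi, dt_v[i]))^2)
    }
    opt <- tryCatch(optimize(sse, lower = dt_v[i], upper = dp_max, tol = 1e-9),
                    error = function(e) NULL)
    if (!is.null(opt) && is.finite(opt$minimum)) {
      dp[i] <- opt$minimum
      dp_valid[i] <- TRUE
    }
  }

  mk <- function(vals, fill = NA_real_) {
    a <- array(fill, dim = sm$shape)
    a[sm$vox] <- vals
    a
  }
  structure(list(m0 = mk(m0), fp = mk(fp), dp = mk(dp), dt = mk(dt_v),
                 m_int = mk(m_int), fp_raw = mk(fp_raw),
                 valid = mk(valid_v, FALSE) & TRUE,
                 dp_valid = mk(dp_valid, FALSE) & TRUE,
                 b_threshold = b_threshold),
            class = "ivim_fit")
}
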
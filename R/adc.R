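# Monoexponential ADC fitting.

# Weighted log-linear least squares of log-signal versus b, weights
# proportional to the squared signal (first-order equivalent to nonlinear
# least squares on the signal scale). Operates on a voxels x b matrix;
# non-positive signals drop only the offending point. Returns slope-derived
# D, intercept-derived S0, weighted R^2 and per-voxel usable point count.
loglinear_fit <- function(sig, b) {
  w <- sig^2
  ok <- is.finite(sig) & sig > 0
  w[!ok] <- 0
  y <- log(pmax(sig, .Machine$double.xmin))
  y[!ok] <- 0
  bm <- matrix(b, nrow = nrow(sig), ncol = length(b), byrow = TRUE)
  sw <- rowSums(w)
  sb <- rowSums(w * bm)
  sbb <- rowSums(w * bm^2)
  sy <- rowSums(w * y)
  sby <- rowSums(w * bm * y)
  denom <- sw * sbb - sb^2
  slope <- ifelse(denom > 0, (sw * sby - sb * sy) / denom, NA_real_)
  intercept <- ifelse(sw > 0, (sy - slope * sb) / sw, NA_real_)
  # weighted R^2 around the weighted mean of y
  ybar <- ifelse(sw > 0, sy / sw, NA_real_)
  sst <- rowSums(w * (y - ybar)^2)
  fit <- intercept + slope * bm
  sse <- rowSums(w * (y - fit)^2)
  rsq <- ifelse(sst > 0, pmax(0, pmin(1, 1 - sse / sst)), 1)
  list(slope = slope, intercept = intercept, rsq = rsq,
       n_used = rowSums(ok & w > 0))
}

series_matrix <- function(series, mask = NULL) {
  d <- series$data
  shape <- dim(d)[1:3]
  nb <- dim(d)[4]
  if (is.null(mask)) mask <- series$mask
  vox <- if (is.null(mask)) seq_len(prod(shape)) else which(mask)
  assert_that(length(vox) > 0, "mask selects no voxels")
  m <- matrix(d, nrow = prod(shape), ncol = nb)[vox, , drop = FALSE]
  list(m = m, vox = vox, shape = shape)
}

#' Monoexponential ADC map
#'
#' Fits \eqn{S(b) = S_0 e^{-b \cdot ADC}} per voxel over all b-values by
#' weighted log-linear least squares (weights proportional to the squared
#' signal). Voxels with fewer than two usable (positive-signal) points are
#' flagged invalid and carry `NA`; a negative fitted decay is clamped to 0
#' (ADC is non-negative by definition).
#'
#' @param series A [dwi_series()].
#' @param mask Optional ROI restricting the fit; defaults to the series
#'   mask, else the whole volume.
#' @return Object of class `adc_map` with 3-D arrays `adc` (mm^2/s), `s0`,
#'   `rsq` and logical `valid`.
#' @examples
#' ph <- make_phantom(make_protocol(dwi_shape = c(16, 16, 1)),
#'                    graft = list(fp = 0))
#' fit <- fit_adc(simulate_dwi(ph))
#' @export
fit_adc <- function(series, mask = NULL) {
  b <- series$protocol$b_values
  if (length(b) < 2L) stop_renalmr("fit_adc: need at least 2 b-values")
  sm <- series_matrix(series, mask)
  if (all(sm$m <= 0)) stop_renalmr("fit_adc: fewer than 2 usable b-values in every voxel")
  ll <- loglinear_fit(sm$m, b)
  valid_v <- ll$n_used >= 2L & is.finite(ll$slope)

  mk <- function(vals) {
    a <- array(NA_real_, dim = sm$shape)
    a[sm$vox] <- vals
    a
  }
  adc <- pmax(-ll$slope, 0)
  adc[!valid_v] <- NA_real_
  valid <- array(FALSE, dim = sm$shape)
  valid[sm$vox] <- valid_v
  structure(list(adc = mk(adc), s0 = mk(exp(ll$intercept)),
                 rsq = mk(ll$rsq), valid = valid),
            class = "adc_map")
}
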
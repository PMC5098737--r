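#' Construct a diffusion-weighted image series
#'
#' @param data 4-D numeric array (x, y, slice, b-index), non-negative signal.
#' @param protocol [make_protocol()] object; `length(protocol$b_values)` must
#'   equal the fourth dimension of `data`.
#' @param mask Optional logical/binary 3-D ROI array on the same grid.
#' @return Object of class `dwi_series`.
#' @export
dwi_series <- function(data, protocol, mask = NULL) {
  assert_that(length(dim(data)) == 4L, "DWI data must be a 4-D array (x, y, slice, b)")
  assert_that(dim(data)[4] == length(protocol$b_values),
              sprintf("dimension error: %d volumes but %d b-values",
                      dim(data)[4], length(protocol$b_values)))
  assert_that(all(data >= 0, na.rm = TRUE), "DWI signals must be non-negative")
  if (!is.null(mask)) {
    assert_that(all(dim(mask) == dim(data)[1:3]),
                "dimension error: mask grid does not match DWI grid")
    mask <- array(as.logical(mask), dim = dim(mask))
  }
  structure(list(data = data, protocol = protocol, mask = mask),
            class = "dwi_series")
}

#' Simulate a DWI series from a phantom (biexponential IVIM signal)
#'
#' Voxel signal follows the two-compartment intravoxel-incoherent-motion
#' model
#' \deqn{M(b) = M_0 \left( f_p e^{-b D_p} + (1 - f_p) e^{-b D_t} \right)}
#' evaluated exactly at every protocol b-value. With `noise_sd > 0`,
#' magnitude (Rician) noise is added: the reported signal is the modulus of
#' the complex signal after independent Gaussian perturbations of the real
#' and imaginary channels, which is how MR magnitude images behave.
#'
#' @param phantom [make_phantom()] object supplying `m0_map`, `fp_map`,
#'   `dp_map`, `dt_map`.
#' @param protocol Acquisition protocol; defaults to the phantom's.
#' @param noise_sd Gaussian channel noise SD in signal units (>= 0).
#' @param seed Integer seed for reproducible noise; same seed, same series.
#' @return A [dwi_series()] whose `mask` is the phantom's whole-kidney ROI.
#' @examples
#' ph <- make_phantom(make_protocol(dwi_shape = c(16, 16, 1)))
#' s <- simulate_dwi(ph, noise_sd = 0)
#' @export
simulate_dwi <- function(phantom, protocol = phantom$protocol,
                         noise_sd = 0, seed = NULL) {
  assert_that(noise_sd >= 0, "noise_sd must be >= 0")
  assert_that(all(dim(phantom$m0_map) == protocol$dwi_shape),
              "dimension error: phantom grid does not match protocol dwi_shape")
  b <- protocol$b_values
  shape <- dim(phantom$m0_map)
  out <- array(0, dim = c(shape, length(b)))
  for (i in seq_along(b)) {
    out[, , , i] <- phantom$m0_map *
      (phantom$fp_map * exp(-b[i] * phantom$dp_map) +
         (1 - phantom$fp_map) * exp(-b[i] * phantom$dt_map))
  }
  if (noise_sd > 0) {
    out <- with_seed(seed, {
      n <- length(out)
      re <- out + rnorm(n, sd = noise_sd)
      im <- rnorm(n, sd = noise_sd)
      array(sqrt(re^2 + im^2), dim = dim(out))
    })
  }
  dwi_series(out, protocol, mask = phantom$kidney_mask)
}

# closed-form IVIM signal, used by simulators and fitters
ivim_signal <- function(b, m0, fp, dp, dt) {
  m0 * (fp * exp(-b * dp) + (1 - fp) * exp(-b * dt))
}
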
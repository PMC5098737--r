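#' MR acquisition protocol
#'
#' Bundle of acquisition parameters shared by the DWI and DCE simulators and
#' fitters. The defaults reproduce the study protocol this package targets:
#' a ten-b-value echo-planar diffusion acquisition (b = 0, 10, 30, 50, 80,
#' 120, 200, 400, 600, 800 s/mm\eqn{^2}) and a dynamic contrast-enhanced
#' acquisition at 1.5 s temporal resolution over 6 minutes (240 frames).
#'
#' @param b_values Diffusion weightings in s/mm\eqn{^2}; must be strictly
#'   increasing and start at 0.
#' @param frame_interval DCE temporal resolution in seconds (> 0).
#' @param duration Total DCE acquisition time in seconds; used to derive
#'   `n_frames` when that is not given.
#' @param n_frames Number of DCE frames; default `round(duration / frame_interval)`.
#' @param dwi_shape,dce_shape Integer triplets, grid dimensions in voxels.
#' @param voxel_size Voxel edge lengths in mm (x, y, slice).
#'
#' @return An object of class `mr_protocol`.
#' @examples
#' p <- make_protocol()
#' p$b_values
#' p$n_frames  # 240
#' @export
make_protocol <- function(b_values = c(0, 10, 30, 50, 80, 120, 200, 400, 600, 800),
                          frame_interval = 1.5,
                          duration = 360,
                          n_frames = NULL,
                          dwi_shape = c(64L, 64L, 4L),
                          dce_shape = c(64L, 64L, 4L),
                          voxel_size = c(0.6, 0.6, 3)) {
  b_values <- as.numeric(b_values)
  if (length(b_values) < 2L || anyNA(b_values)) {
    stop_renalmr("protocol validation: need at least two finite b-values")
  }
  if (b_values[1] != 0) {
    stop_renalmr("protocol validation: first b-value must be 0 (unweighted reference)")
  }
  if (any(diff(b_values) <= 0)) {
    stop_renalmr("protocol validation: b-values must be strictly increasing")
  }
  if (!is.numeric(frame_interval) || frame_interval <= 0) {
    stop_renalmr("protocol validation: frame_interval must be > 0")
  }
  if (is.null(n_frames)) n_frames <- as.integer(round(duration / frame_interval))
  n_frames <- as.integer(n_frames)
  if (n_frames < 3L) stop_renalmr("protocol validation: need at least 3 DCE frames")
  assert_that(length(dwi_shape) == 3L && all(dwi_shape >= 1),
              "protocol validation: dwi_shape must be a positive integer triplet")
  assert_that(length(dce_shape) == 3L && all(dce_shape >= 1),
              "protocol validation: dce_shape must be a positive integer triplet")
  assert_that(length(voxel_size) == 3L && all(voxel_size > 0),
              "protocol validation: voxel_size must be a positive mm triplet")

  structure(
    list(
      b_values = b_values,
      frame_interval = frame_interval,
      n_frames = n_frames,
      dwi_shape = as.integer(dwi_shape),
      dce_shape = as.integer(dce_shape),
      voxel_size = as.numeric(voxel_size)
    ),
    class = "mr_protocol"
  )
}

#' @export
print.mr_protocol <- function(x, ...) {
  cat("MR acquisition protocol\n")
  cat("  b-values (s/mm^2):", paste(x$b_values, collapse = ", "), "\n")
  cat(sprintf("  DCE: %d frames @ %.2f s (%.0f s total)\n",
              x$n_frames, x$frame_interval, x$n_frames * x$frame_interval))
  cat("  DWI grid:", paste(x$dwi_shape, collapse = "x"),
      " DCE grid:", paste(x$dce_shape, collapse = "x"),
      " voxel (mm):", paste(x$voxel_size, collapse = "x"), "\n")
  invisible(x)
}
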
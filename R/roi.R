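# ROI-level summaries of parametric maps.

summarize_one <- function(map, valid, mask, metric, scale = 1, unit = "") {
  sel <- mask & valid & is.finite(map)
  n <- sum(sel)
  vals <- map[sel] * scale
  data.frame(metric = metric,
             mean = if (n > 0) mean(vals) else NA_real_,
             sd = if (n > 0) sd0(vals) else NA_real_,
             n_voxels = n, unit = unit,
             stringsAsFactors = FALSE)
}

#' Summarize a parametric map over a region of interest
#'
#' Mean, sample SD and voxel count over the valid voxels of the mask.
#' Diffusivities are reported in mm^2/s x 10^-3 (the ROI-level reporting
#' convention), perfusion metrics in their native units.
#'
#' @param map An `adc_map`, `ivim_fit`, `perfusion_map`, or a plain numeric
#'   array.
#' @param mask Logical/binary ROI array; must intersect valid voxels.
#' @param roi_name Label used in error messages and the output.
#' @param ... Unused.
#' @return A `data.frame` with one row per metric: `metric`, `mean`, `sd`,
#'   `n_voxels`, `unit`.
#' @export
roi_summary <- function(map, mask, roi_name = "ROI", ...) {
  UseMethod("roi_summary")
}

check_roi <- function(valid, mask, roi_name) {
  assert_that(all(dim(mask) == dim(valid)),
              sprintf("roi_summary: mask grid does not match map grid (%s)", roi_name))
  mask <- array(as.logical(mask), dim = dim(mask))
  if (!any(mask & valid)) {
    stop_renalmr(sprintf("roi_summary: ROI '%s' contains no valid voxels", roi_name))
  }
  mask
}

#' @rdname roi_summary
#' @export
roi_summary.adc_map <- function(map, mask, roi_name = "ROI", ...) {
  mask <- check_roi(map$valid, mask, roi_name)
  out <- summarize_one(map$adc, map$valid, mask, "adc",
                       scale = 1e3, unit = "mm^2/s x10^-3")
  out$roi <- roi_name
  out
}

#' @rdname roi_summary
#' @export
roi_summary.ivim_fit <- function(map, mask, roi_name = "ROI", ...) {
  mask <- check_roi(map$valid, mask, roi_name)
  out <- rbind(
    summarize_one(map$fp, map$valid, mask, "fp", unit = "fraction"),
    summarize_one(map$dt, map$valid, mask, "dt", scale = 1e3, unit = "mm^2/s x10^-3"),
    summarize_one(map$dp, map$dp_valid, mask, "dp", scale = 1e3, unit = "mm^2/s x10^-3")
  )
  out$roi <- roi_name
  out
}

#' @rdname roi_summary
#' @export
roi_summary.perfusion_map <- function(map, mask, roi_name = "ROI", ...) {
  mask <- check_roi(map$valid, mask, roi_name)
  out <- rbind(
    summarize_one(map$fp, map$valid, mask, "plasma_flow", unit = "ml/100ml/min"),
    summarize_one(map$ecv, map$valid, mask, "ecv", unit = "ml/100ml"),
    summarize_one(map$mtt, map$valid, mask, "mtt", unit = "min")
  )
  out$roi <- roi_name
  out
}

#' @rdname roi_summary
#' @export
roi_summary.default <- function(map, mask, roi_name = "ROI", ...) {
  assert_that(is.numeric(map), "roi_summary: map must be numeric")
  valid <- is.finite(map)
  dim(valid) <- dim(map)
  mask <- check_roi(valid, mask, roi_name)
  out <- summarize_one(map, valid, mask, "value")
  out$roi <- roi_name
  out
}
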
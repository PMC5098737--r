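# NIfTI-1 and text I/O for series, masks, b-value tables and cohort CSVs.

as_nifti_image <- function(arr, voxel_size, frame_interval = NULL) {
  img <- RNifti::asNifti(arr)
  pd <- c(voxel_size, frame_interval %||% 1)[seq_len(length(dim(arr)))]
  RNifti::pixdim(img) <- pd
  img
}

affine_of <- function(path) {
  structure(RNifti::xform(RNifti::readNifti(path)), code = NULL)
}

check_affines <- function(paths, tol = 1e-4) {
  if (length(paths) < 2) return(invisible(TRUE))
  ref <- affine_of(paths[1])
  for (p in paths[-1]) {
    if (max(abs(affine_of(p) - ref)) > tol) {
      stop_renalmr(sprintf("affine mismatch beyond tolerance %g between '%s' and '%s'",
                           tol, paths[1], p))
    }
  }
  invisible(TRUE)
}

#' Write / read b-value tables (FSL bval dialect)
#'
#' One line of space-separated values in s/mm^2.
#' @param b_values Numeric vector.
#' @param path File path.
#' @return `read_bvals` returns a numeric vector.
#' @export
write_bvals <- function(b_values, path) {
  writeLines(paste(format(b_values, trim = TRUE, scientific = FALSE),
                   collapse = " "), path)
  invisible(path)
}

#' @rdname write_bvals
#' @export
read_bvals <- function(path) {
  if (!file.exists(path)) stop_renalmr(sprintf("unreadable b-value file: '%s'", path))
  as.numeric(strsplit(trimws(readLines(path, n = 1L)), "\\s+")[[1]])
}

#' Write a DWI series to NIfTI + bval files
#'
#' @param series A [dwi_series()].
#' @param nii_path Output NIfTI path (`.nii` or `.nii.gz`).
#' @param bval_path Output b-value table path; default replaces the NIfTI
#'   extension with `.bval`.
#' @return Invisibly, the NIfTI path.
#' @export
write_dwi <- function(series, nii_path, bval_path = NULL) {
  bval_path <- bval_path %||% sub("\\.nii(\\.gz)?$", ".bval", nii_path)
  img <- as_nifti_image(series$data, series$protocol$voxel_size, 1)
  RNifti::writeNifti(img, nii_path)
  write_bvals(series$protocol$b_values, bval_path)
  invisible(nii_path)
}

#' Read a DWI series from NIfTI + bval files
#'
#' @param nii_path 4-D NIfTI path.
#' @param bval_path b-value table (FSL dialect).
#' @param mask_path Optional mask NIfTI; must share the affine within 1e-4.
#' @param protocol Optional protocol template for non-spatial parameters.
#' @return A [dwi_series()].
#' @export
read_dwi <- function(nii_path, bval_path, mask_path = NULL, protocol = NULL) {
  if (!file.exists(nii_path)) stop_renalmr(sprintf("unreadable DWI file: '%s'", nii_path))
  img <- RNifti::readNifti(nii_path)
  arr <- as.array(img)
  if (length(dim(arr)) != 4L) {
    stop_renalmr(sprintf("DWI series '%s' is not 4-D", nii_path))
  }
  b <- read_bvals(bval_path)
  if (length(b) != dim(arr)[4]) {
    stop_renalmr(sprintf("bval mismatch: '%s' lists %d values but '%s' has %d volumes",
                         bval_path, length(b), nii_path, dim(arr)[4]))
  }
  vs <- RNifti::pixdim(img)[1:3]
  proto <- make_protocol(b_values = b,
                         frame_interval = (protocol %||% make_protocol())$frame_interval,
                         dwi_shape = dim(arr)[1:3], dce_shape = dim(arr)[1:3],
                         voxel_size = vs)
  mask <- NULL
  if (!is.null(mask_path)) {
    check_affines(c(nii_path, mask_path))
    mask <- read_mask(mask_path)
    assert_that(all(dim(mask) == dim(arr)[1:3]),
                sprintf("dimension error: mask '%s' does not match '%s'", mask_path, nii_path))
  }
  dwi_series(arr, proto, mask = mask)
}

#' Write / read a DCE series as NIfTI
#'
#' Frame interval is stored in the 4th pixdim slot.
#' @param series A [dce_series()].
#' @param nii_path NIfTI path.
#' @return Invisibly, the path.
#' @export
write_dce <- function(series, nii_path) {
  vs <- if (!is.null(series$protocol)) series$protocol$voxel_size else c(1, 1, 1)
  img <- as_nifti_image(series$data, vs, series$frame_interval)
  RNifti::writeNifti(img, nii_path)
  invisible(nii_path)
}

#' @rdname write_dce
#' @param baseline_frames Pre-contrast frame count of the stored series.
#' @param frame_interval Override for the frame interval (s); default read
#'   from the file's pixdim.
#' @export
read_dce <- function(nii_path, baseline_frames, frame_interval = NULL) {
  if (!file.exists(nii_path)) stop_renalmr(sprintf("unreadable DCE file: '%s'", nii_path))
  img <- RNifti::readNifti(nii_path)
  arr <- as.array(img)
  if (length(dim(arr)) != 4L) stop_renalmr(sprintf("DCE series '%s' is not 4-D", nii_path))
  dt <- frame_interval %||% RNifti::pixdim(img)[4]
  dce_series(arr, dt, baseline_frames)
}

#' Read a binary ROI mask from NIfTI
#'
#' Non-binary values are coerced by a `> 0.5` threshold with a warning.
#' @param path Mask NIfTI path.
#' @return Logical 3-D array.
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop_renalmr(sprintf("unreadable mask file: '%s'", path))
  arr <- as.array(RNifti::readNifti(path))
  if (length(dim(arr)) > 3L) arr <- arr[, , , 1]
  vals <- unique(as.vector(arr))
  if (!all(vals %in% c(0, 1))) {
    warning(sprintf("mask '%s' is not binary; coercing by > 0.5 threshold", path))
  }
  array(arr > 0.5, dim = dim(arr)[1:3])
}

#' Write a mask to NIfTI
#' @param mask Logical/binary 3-D array.
#' @param path Output path.
#' @param voxel_size mm triplet.
#' @export
write_mask <- function(mask, path, voxel_size = c(1, 1, 1)) {
  img <- as_nifti_image(array(as.numeric(mask), dim = dim(mask)), voxel_size)
  RNifti::writeNifti(img, path)
  invisible(path)
}

.cohort_csv_cols <- c("animal_id", "group", "adc", "plasma_flow",
                      "intimal_arteritis", "interstitial_inflammation",
                      "tubulitis", "periarteritis", "f480_pct")

#' Write / read the cohort table CSV
#'
#' One header row; columns exactly `animal_id, group, adc, plasma_flow,
#' intimal_arteritis, interstitial_inflammation, tubulitis, periarteritis,
#' f480_pct` (ADC in mm^2/s x 10^-3, plasma flow in ml/100ml/min, scores
#' 0-3, F4/80 in % area).
#'
#' @param cohort Cohort `data.frame`.
#' @param path CSV path.
#' @return `read_cohort` returns the validated `data.frame`.
#' @export
write_cohort <- function(cohort, path) {
  missing <- setdiff(.cohort_csv_cols, names(cohort))
  assert_that(length(missing) == 0,
              paste("write_cohort: missing columns:", paste(missing, collapse = ", ")))
  write.csv(cohort[, .cohort_csv_cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop_renalmr(sprintf("unreadable cohort file: '%s'", path))
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(.cohort_csv_cols, names(df))
  assert_that(length(missing) == 0,
              sprintf("cohort file '%s' lacks columns: %s", path,
                      paste(missing, collapse = ", ")))
  df
}

#' Write a parametric map bundle to NIfTI float maps with a provenance sidecar
#'
#' @param maps Named list of 3-D numeric arrays sharing one grid.
#' @param dir Output directory (created if needed).
#' @param voxel_size mm triplet for the affine.
#' @param provenance Named list (seed, config hash, version, ...) written as
#'   a JSON sidecar next to the maps.
#' @return Character vector of written map paths.
#' @export
write_map_bundle <- function(maps, dir, voxel_size = c(1, 1, 1),
                             provenance = list()) {
  dims <- unique(lapply(maps, dim))
  assert_that(length(dims) == 1L, "map bundle: all maps must share one grid")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(names(maps), function(nm) {
    p <- file.path(dir, paste0(nm, ".nii.gz"))
    RNifti::writeNifti(as_nifti_image(maps[[nm]], voxel_size), p, datatype = "float")
    p
  }, character(1))
  provenance$software <- paste("renalmr", as.character(utils::packageVersion("renalmr")))
  jsonlite::write_json(provenance, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths
}
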
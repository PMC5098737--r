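#' Digital kidney phantom with known ground truth
#'
#' Builds a simple 3-D phantom holding per-voxel ground-truth parameter maps
#' for the DWI and DCE simulators: two ellipsoidal "kidneys" (the transplanted
#' graft and one native kidney) on a zero background, a renal-pelvis region
#' inside the graft that is excluded from the whole-kidney ROI, and a small
#' arterial region that carries the arterial input function in DCE series.
#' The geometry is a rendering/ROI convenience, not an anatomical claim.
#'
#' Tissue parameters are uniform within each compartment. Defaults describe a
#' rejecting untreated allograft next to a healthy native kidney: graft tissue
#' diffusivity 0.63e-3 mm^2/s and plasma flow 23.48 ml/100ml/min versus
#' 1.17e-3 mm^2/s and 46.65 ml/100ml/min for the native kidney. The pelvis is
#' modelled as free fluid (high diffusivity, no perfusion).
#'
#' @param protocol An [make_protocol()] object; sets the grid.
#' @param graft,native Named lists of compartment parameters with elements
#'   `dt`, `fp`, `dp` (IVIM tissue diffusivity mm^2/s, perfusion fraction,
#'   pseudo-diffusivity mm^2/s), `fp_dce` (plasma flow, ml/100ml/min) and
#'   `ecv` (extracellular volume, ml/100ml). Partial lists override defaults.
#' @param m0 Baseline (b = 0) signal amplitude inside tissue, arbitrary units.
#'
#' @return An object of class `mr_phantom`: parameter maps (`m0_map`,
#'   `fp_map`, `dp_map`, `dt_map`, `fp_dce_map`, `ecv_map`) and logical masks
#'   (`kidney_mask` = graft excluding pelvis, `native_mask`, `pelvis_mask`,
#'   `artery_mask`), all on the protocol's DWI grid.
#' @examples
#' ph <- make_phantom(make_protocol(dwi_shape = c(32, 32, 2)))
#' sum(ph$kidney_mask)
#' @export
make_phantom <- function(protocol = make_protocol(),
                         graft = list(),
                         native = list(),
                         m0 = 1000) {
  graft <- modifyList(
    list(dt = 0.63e-3, fp = 0.12, dp = 10e-3, fp_dce = 23.48, ecv = 30),
    graft
  )
  native <- modifyList(
    list(dt = 1.17e-3, fp = 0.15, dp = 10e-3, fp_dce = 46.65, ecv = 30),
    native
  )
  for (comp in list(graft, native)) {
    assert_that(all(unlist(comp) >= 0), "phantom parameters must be non-negative")
    if (comp$fp > 0) {
      assert_that(comp$dp > comp$dt,
                  "phantom invariant violated: dp must exceed dt where fp > 0")
    }
    assert_that(comp$fp <= 1, "perfusion fraction fp must lie in [0, 1]")
  }

  shape <- protocol$dwi_shape
  nx <- shape[1]; ny <- shape[2]; nz <- shape[3]
  ix <- (seq_len(nx) - 0.5) / nx
  iy <- (seq_len(ny) - 0.5) / ny
  iz <- if (nz > 1) (seq_len(nz) - 0.5) / nz else 0.5

  ellipsoid <- function(cx, cy, ax, ay) {
    d2 <- outer(((ix - cx) / ax)^2, ((iy - cy) / ay)^2, `+`)
    arr <- array(FALSE, dim = shape)
    zc <- if (nz > 1) 1 - ((iz - 0.5) / 0.45)^2 else rep(1, nz)
    for (k in seq_len(nz)) arr[, , k] <- d2 <= pmax(zc[k], 0)
    arr
  }

  graft_all  <- ellipsoid(0.30, 0.55, 0.20, 0.28)
  native_all <- ellipsoid(0.72, 0.55, 0.16, 0.22)
  pelvis     <- ellipsoid(0.30, 0.55, 0.07, 0.10)
  pelvis     <- pelvis & graft_all
  # small arterial block in the background, clear of both kidneys
  artery <- array(FALSE, dim = shape)
  ax_i <- pmax(1L, round(0.5 * nx)) + c(0L, 1L)
  ay_i <- pmax(1L, round(0.12 * ny)) + c(0L, 1L)
  artery[ax_i[ax_i <= nx], ay_i[ay_i <= ny], ] <- TRUE
  artery <- artery & !graft_all & !native_all

  fill <- function(graft_val, native_val, pelvis_val) {
    m <- array(0, dim = shape)
    m[graft_all] <- graft_val
    m[native_all] <- native_val
    m[pelvis] <- pelvis_val
    m
  }

  structure(
    list(
      protocol = protocol,
      m0_map = fill(m0, m0, m0),
      fp_map = fill(graft$fp, native$fp, 0),
      dp_map = fill(graft$dp, native$dp, 0),
      dt_map = fill(graft$dt, native$dt, 3.0e-3),
      fp_dce_map = fill(graft$fp_dce, native$fp_dce, 0),
      ecv_map = fill(graft$ecv, native$ecv, 0),
      kidney_mask = graft_all & !pelvis,
      native_mask = native_all,
      pelvis_mask = pelvis,
      artery_mask = artery,
      graft = graft,
      native = native
    ),
    class = "mr_phantom"
  )
}

#' @export
print.mr_phantom <- function(x, ...) {
  cat("Digital kidney phantom", paste(dim(x$m0_map), collapse = "x"), "\n")
  cat(sprintf("  graft:  Dt=%.3g mm^2/s fp=%.2f Dp=%.3g  FP=%.4g ml/100ml/min ECV=%.4g ml/100ml\n",
              x$graft$dt, x$graft$fp, x$graft$dp, x$graft$fp_dce, x$graft$ecv))
  cat(sprintf("  native: Dt=%.3g mm^2/s fp=%.2f Dp=%.3g  FP=%.4g ml/100ml/min ECV=%.4g ml/100ml\n",
              x$native$dt, x$native$fp, x$native$dp, x$native$fp_dce, x$native$ecv))
  cat(sprintf("  ROI voxels: graft %d (pelvis %d excluded), native %d, artery %d\n",
              sum(x$kidney_mask), sum(x$pelvis_mask), sum(x$native_mask), sum(x$artery_mask)))
  invisible(x)
}
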
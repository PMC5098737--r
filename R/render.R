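# PNG rendering of parametric maps.

#' Render parametric maps as PNG images with a colorbar
#'
#' One PNG per map, showing the requested slice with a labelled colorbar.
#' Windowing clips for display only; map data are untouched. Output is
#' deterministic for fixed inputs (fixed device size, palette and layout).
#'
#' @param maps Named list of 3-D numeric arrays (e.g. `adc`, `plasma_flow`).
#' @param dir Output directory.
#' @param slice_index Slice to display; default middle slice.
#' @param window Optional `c(low, high)` display window applied to all maps.
#' @param units Optional named character vector of unit labels per map.
#' @return Named character vector of PNG paths.
#' @export
render_maps <- function(maps, dir, slice_index = NULL, window = NULL,
                        units = NULL) {
  assert_that(length(maps) > 0 && !is.null(names(maps)),
              "render_maps: maps must be a named list")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vapply(names(maps), function(nm) {
    m <- maps[[nm]]
    assert_that(length(dim(m)) == 3L, sprintf("map '%s' must be 3-D", nm))
    nz <- dim(m)[3]
    k <- slice_index %||% ceiling(nz / 2)
    assert_that(k >= 1 && k <= nz,
                sprintf("slice %s out of range 1..%d for map '%s'", k, nz, nm))
    sl <- m[, , k]
    rng <- if (is.null(window)) range(sl, finite = TRUE) else window
    if (!is.finite(diff(rng)) || diff(rng) <= 0) rng <- rng[1] + c(0, 1)
    sl <- pmin(pmax(sl, rng[1]), rng[2])
    sl[!is.finite(sl)] <- rng[1]
    unit <- if (!is.null(units) && nm %in% names(units)) units[[nm]] else ""
    path <- file.path(dir, paste0(nm, ".png"))
    png(path, width = 640, height = 520)
    on.exit(dev.off(), add = TRUE)
    pal <- hcl.colors(128, "viridis")
    layout(matrix(c(1, 2), nrow = 1), widths = c(5, 1))
    par(mar = c(2, 2, 3, 1))
    image(sl, col = pal, zlim = rng, axes = FALSE, asp = dim(sl)[2] / dim(sl)[1])
    title(main = sprintf("%s (slice %d)%s", nm, k,
                         if (nzchar(unit)) paste0(" [", unit, "]") else ""))
    par(mar = c(2, 1, 3, 3))
    zseq <- seq(rng[1], rng[2], length.out = length(pal))
    image(1, zseq, matrix(zseq, nrow = 1), col = pal, axes = FALSE,
          xlab = "", ylab = "")
    axis(4, at = pretty(rng))
    path
  }, character(1))
}
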
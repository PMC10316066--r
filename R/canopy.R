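#' Canopy cover of a plot window
#'
#' Canopy cover is the percentage of valid plot pixels whose canopy height
#' strictly exceeds the threshold: CC = 100 * px2m / pxtot, where px2m
#' counts pixels with height > threshold and pxtot the non-nodata pixels.
#' The conventional threshold is 2 m, applied strictly (a pixel at exactly
#' 2.00 m does not count as canopy). Computed on the finest available CHM
#' in practice; any cell size is accepted and recorded.
#'
#' @param window a `plot_window` from [extract_plot_window()].
#' @param threshold canopy height threshold in metres.
#' @return List of class `canopy_cover` with `plot_id`, `cc` (percent,
#'   0-100), `px2m`, `pxtot`, `threshold` and `cell_size`.
#' @export
canopy_cover <- function(window, threshold = 2) {
  stopifnot(inherits(window, "plot_window"))
  h <- window$heights
  if (length(h) < 1L) stop("empty window")
  px2m <- sum(h > threshold)
  structure(list(plot_id = window$plot_id,
                 cc = 100 * px2m / length(h),
                 px2m = px2m, pxtot = length(h),
                 threshold = threshold,
                 cell_size = window$source_cell_size),
            class = "canopy_cover")
}

#' @export
print.canopy_cover <- function(x, ...) {
  cat(sprintf("plot %s: canopy cover %.1f%% (%d/%d pixels > %g m @ %g m cells)\n",
              x$plot_id, x$cc, x$px2m, x$pxtot, x$threshold, x$cell_size))
  invisible(x)
}

#' Per-plot canopy cover table
#'
#' @param grid fine-resolution [raster_grid()] CHM.
#' @param plots a `plot_geometry` data frame.
#' @param threshold canopy height threshold in metres.
#' @return Data frame `plot_id, canopy_cover_pct, threshold_m, cell_size_m`.
#' @export
canopy_cover_table <- function(grid, plots, threshold = 2) {
  rows <- lapply(seq_len(nrow(plots)), function(i) {
    cc <- canopy_cover(extract_plot_window(grid, plots[i, ]), threshold)
    data.frame(plot_id = cc$plot_id, canopy_cover_pct = cc$cc,
               threshold_m = cc$threshold, cell_size_m = cc$cell_size)
  })
  do.call(rbind, rows)
}
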
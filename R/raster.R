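#' Construct a georeferenced single-band height grid
#'
#' A `raster_grid` holds a matrix of canopy heights (metres) on square cells
#' in a projected (planar, metric) coordinate system. Row 1 is the
#' northernmost row; columns increase eastward. Missing cells are stored as
#' `NA` in memory and as the `nodata` sentinel on disk.
#'
#' @param values numeric matrix of heights (metres); `NA` marks nodata cells.
#' @param cell_size cell edge length in metres (> 0, square cells only).
#' @param origin numeric length-2: easting/northing of the upper-left corner
#'   of the upper-left cell.
#' @param nodata numeric sentinel used when the grid is written to disk.
#' @param crs_id optional text identifier of the projected reference system
#'   (e.g. `"EPSG:32632"`).
#' @return An object of class `raster_grid`.
#' @export
raster_grid <- function(values, cell_size, origin = c(0, 0),
                        nodata = -9999, crs_id = "") {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop("grid must have at least one row and one column")
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("`cell_size` must be a single positive number")
  if (length(origin) != 2L || !is.numeric(origin))
    stop("`origin` must be numeric of length 2 (easting, northing)")
  if (any(values[!is.na(values)] < 0))
    stop("heights must be non-negative")
  structure(
    list(values = unname(values), cell_size = as.numeric(cell_size),
         origin = as.numeric(origin), nodata = as.numeric(nodata),
         crs_id = as.character(crs_id)),
    class = "raster_grid")
}

#' @export
print.raster_grid <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("raster_grid: %d x %d cells @ %g m\n", nrow(x$values),
              ncol(x$values), x$cell_size))
  cat(sprintf("  origin (UL corner): E %.2f, N %.2f%s\n", x$origin[1],
              x$origin[2],
              if (nzchar(x$crs_id)) paste0("  [", x$crs_id, "]") else ""))
  cat(sprintf("  heights: %s, nodata cells: %d\n",
              if (length(v)) sprintf("%.2f..%.2f m", min(v), max(v))
              else "none valid",
              sum(is.na(x$values))))
  invisible(x)
}

#' @export
dim.raster_grid <- function(x) dim(x$values)

# 17 significant digits round-trip IEEE doubles bit-exactly
.fmt_full <- function(x) sprintf("%.17g", x)

#' Write a raster to an ESRI ASCII grid file
#'
#' The grid is serialized as a plain-text ESRI ASCII grid (`.asc`), a
#' standard single-band georeferenced format readable by QGIS, GDAL and most
#' GIS tools. Values are written at full double precision so a write/read
#' round trip is bit-exact. If `crs_id` is non-empty it is stored in a
#' sidecar file `<path without extension>.prj`.
#'
#' @param grid a [raster_grid()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_raster <- function(grid, path) {
  stopifnot(inherits(grid, "raster_grid"))
  v <- grid$values
  con <- file(path, open = "wt")
  on.exit(close(con))
  yll <- grid$origin[2] - nrow(v) * grid$cell_size
  writeLines(c(
    paste("ncols", ncol(v)),
    paste("nrows", nrow(v)),
    paste("xllcorner", .fmt_full(grid$origin[1])),
    paste("yllcorner", .fmt_full(yll)),
    paste("cellsize", .fmt_full(grid$cell_size)),
    paste("NODATA_value", .fmt_full(grid$nodata))), con)
  out <- v
  out[is.na(out)] <- grid$nodata
  txt <- matrix(.fmt_full(out), nrow = nrow(out))
  writeLines(apply(txt, 1L, paste, collapse = " "), con)
  if (nzchar(grid$crs_id))
    writeLines(grid$crs_id, sub("\\.[^.]*$", "", path) |> paste0(".prj"))
  invisible(path)
}

#' Read a raster from an ESRI ASCII grid file
#'
#' Reads a single-band ESRI ASCII grid written by [write_raster()] or any
#' GIS tool. Grids with rectangular (non-square) cells — the `dx`/`dy`
#' header variant — are rejected. Cells equal to the nodata sentinel become
#' `NA`.
#'
#' @param path path to an `.asc` file.
#' @return A [raster_grid()].
#' @export
read_raster <- function(path) {
  if (!file.exists(path)) stop("raster file not found: ", path)
  lines <- readLines(path)
  hdr <- list(); i <- 0L
  while (i < length(lines)) {
    parts <- strsplit(trimws(lines[i + 1L]), "\\s+")[[1]]
    if (length(parts) != 2L || is.na(suppressWarnings(as.numeric(parts[2]))) ||
        !grepl("^[A-Za-z_]", parts[1])) break
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1L
  }
  if (!is.null(hdr$dx) || !is.null(hdr$dy))
    stop("non-square cells (dx/dy header) are not supported")
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("not a valid ESRI ASCII grid header: ", path)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  nod <- if (is.null(hdr$nodata_value)) -9999 else hdr$nodata_value
  body <- scan(text = lines[(i + 1L):length(lines)], what = double(),
               quiet = TRUE)
  if (length(body) != nr * nc)
    stop(sprintf("expected %d values, found %d", nr * nc, length(body)))
  vals <- matrix(body, nrow = nr, ncol = nc, byrow = TRUE)
  vals[vals == nod] <- NA_real_
  xll <- if (is.null(hdr$xllcorner)) 0 else hdr$xllcorner
  yll <- if (is.null(hdr$yllcorner)) 0 else hdr$yllcorner
  prj <- sub("\\.[^.]*$", "", path) |> paste0(".prj")
  crs <- if (file.exists(prj)) readLines(prj, n = 1L) else ""
  raster_grid(vals, hdr$cellsize,
              origin = c(xll, yll + nr * hdr$cellsize),
              nodata = nod, crs_id = crs)
}

#' Define a square field plot
#'
#' @param plot_id text identifier.
#' @param center_e,center_n projected plot-centre coordinates (metres).
#' @param side plot edge length in metres; the 100 m default gives the 1 ha
#'   plots used in forest inventories.
#' @return A one-row `data.frame` of class `plot_geometry`.
#' @export
plot_geometry <- function(plot_id, center_e, center_n, side = 100) {
  if (any(side <= 0)) stop("`side` must be positive")
  structure(
    data.frame(plot_id = as.character(plot_id), center_e = center_e,
               center_n = center_n, side = side,
               stringsAsFactors = FALSE),
    class = c("plot_geometry", "data.frame"))
}

#' Read plot definitions from CSV
#'
#' Expects the header `plot_id,center_e,center_n,side`; `side` may be
#' omitted, in which case 100 m is assumed.
#'
#' @param path CSV file path.
#' @return A `plot_geometry` data frame, one row per plot.
#' @export
read_plots <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("plot_id", "center_e", "center_n")
  if (!all(need %in% names(d)))
    stop("plot CSV must have columns plot_id, center_e, center_n[, side]")
  if (is.null(d$side)) d$side <- 100
  plot_geometry(d$plot_id, d$center_e, d$center_n, d$side)
}

#' @rdname read_plots
#' @param plots a `plot_geometry` data frame.
#' @export
write_plots <- function(plots, path) {
  utils::write.csv(plots[, c("plot_id", "center_e", "center_n", "side")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# indices (rows, cols) of cells whose center falls in the plot square.
# Membership: half-open in both axes — a center on the min edge is in, on
# the max edge out — so adjacent plots never share a cell. A relative
# tolerance absorbs coordinate round-off.
.window_indices <- function(grid, center_e, center_n, side) {
  cs <- grid$cell_size
  eps <- cs * 1e-9
  emin <- center_e - side / 2; emax <- center_e + side / 2
  nmin <- center_n - side / 2; nmax <- center_n + side / 2
  ce <- grid$origin[1] + (seq_len(ncol(grid$values)) - 0.5) * cs
  cn <- grid$origin[2] - (seq_len(nrow(grid$values)) - 0.5) * cs
  cols <- which(ce - emin >= -eps & emax - ce > eps)
  rows <- which(cn - nmin >= -eps & nmax - cn > eps)
  list(rows = rows, cols = cols)
}

# sub-matrix of a plot window with NA nodata retained (positional pairing)
.window_matrix <- function(grid, plot) {
  idx <- .window_indices(grid, plot$center_e, plot$center_n, plot$side)
  if (length(idx$rows) == 0L || length(idx$cols) == 0L)
    stop(sprintf("plot '%s' is outside the grid extent", plot$plot_id))
  grid$values[idx$rows, idx$cols, drop = FALSE]
}

#' Extract the pixels of a field plot from a raster
#'
#' Collects every grid cell whose center lies in the plot square
#' (centre +/- side/2 on both axes; a center exactly on the minimum edge is
#' included, on the maximum edge excluded). Nodata cells are excluded from
#' the returned heights but counted.
#'
#' @param grid a [raster_grid()].
#' @param plot a one-row [plot_geometry()] (or any list with `plot_id`,
#'   `center_e`, `center_n`, `side`).
#' @param nodata_warn_frac warn when more than this fraction of the window
#'   is nodata (default 0.5).
#' @return A `plot_window`: list with `plot_id`, `heights` (valid pixel
#'   values, metres), `n_pixels`, `n_nodata` and `source_cell_size`.
#' @export
extract_plot_window <- function(grid, plot, nodata_warn_frac = 0.5) {
  m <- .window_matrix(grid, plot)
  h <- as.vector(m)
  nod <- sum(is.na(h))
  h <- h[!is.na(h)]
  if (length(h) == 0L)
    stop(sprintf("plot '%s' has no usable (non-nodata) pixels", plot$plot_id))
  if (nod > nodata_warn_frac * length(m))
    warning(sprintf("plot '%s': %d of %d cells are nodata", plot$plot_id,
                    nod, length(m)))
  structure(list(plot_id = as.character(plot$plot_id), heights = h,
                 n_pixels = length(h), n_nodata = nod,
                 source_cell_size = grid$cell_size),
            class = "plot_window")
}

#' Aggregate a raster to a coarser cell size
#'
#' Blocks of `factor x factor` cells are collapsed to one output cell by
#' their mean or maximum, ignoring nodata (an all-nodata block stays
#' nodata). Trailing rows/columns that do not fill a whole block are
#' dropped.
#'
#' @param grid a [raster_grid()].
#' @param factor integer >= 2, the linear coarsening factor.
#' @param method `"mean"` or `"max"`.
#' @return A [raster_grid()] with `cell_size * factor`.
#' @export
aggregate_raster <- function(grid, factor, method = c("mean", "max")) {
  method <- match.arg(method)
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 2L) stop("`factor` must be an integer >= 2")
  v <- grid$values
  nr <- (nrow(v) %/% factor) * factor
  nc <- (ncol(v) %/% factor) * factor
  if (nr < factor || nc < factor)
    stop("grid smaller than one aggregation block")
  v <- v[seq_len(nr), seq_len(nc), drop = FALSE]
  fun <- if (method == "mean") {
    function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  } else {
    function(x) if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE)
  }
  # column-major reshape: dims (sub-row, block-row, sub-col, block-col)
  a <- array(v, dim = c(factor, nr %/% factor, factor, nc %/% factor))
  out <- apply(a, c(2L, 4L), fun)
  raster_grid(out, grid$cell_size * factor, origin = grid$origin,
              nodata = grid$nodata, crs_id = grid$crs_id)
}
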
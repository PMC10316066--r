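#' Rao's quadratic entropy of a plot window
#'
#' Rao's Q over the N pixels of a window with uniform pixel abundances
#' p_i = p_j = 1/N:
#'   Q = (1/N^2) * sum_{i,j} d(x_i, x_j)
#' summing over all ordered pairs including i = j (d_ii = 0). With the
#' single-band Euclidean distance d = |x_i - x_j|, Q is the mean absolute
#' pairwise height difference; with the half-squared Euclidean distance
#' d = (x_i - x_j)^2 / 2, Q reduces exactly to the population variance
#' (divisor N) of the window.
#'
#' The Euclidean mode is computed with an O(N log N) sorted-prefix
#' identity, the half-squared mode via the variance identity; both agree
#' with the naive O(N^2) double loop to floating-point accuracy.
#'
#' @param window a `plot_window` from [extract_plot_window()], or a bare
#'   numeric vector of heights.
#' @param distance `"euclidean"` (default) or `"half_squared"`.
#' @return Non-negative Rao's Q (metres for euclidean, square metres for
#'   half_squared).
#' @export
rao_q <- function(window, distance = c("euclidean", "half_squared")) {
  distance <- match.arg(distance)
  x <- if (inherits(window, "plot_window")) window$heights else
    as.numeric(window)
  n <- length(x)
  if (n < 1L) stop("empty window")
  if (n == 1L) return(0)
  if (distance == "euclidean") {
    # sum_{i<j} |x_i - x_j| = sum_k (2k - 1 - n) * x_(k), x sorted ascending
    s <- sort(x)
    2 * sum((2 * seq_len(n) - 1 - n) * s) / n^2
  } else {
    # sum over ordered pairs of (xi - xj)^2 / 2 equals n^2 * Var_pop / n^2
    m <- mean(x)
    mean((x - m)^2)
  }
}

#' Coefficient of variation of a plot window
#'
#' CV = SD / mean of the window's pixel heights. The sample standard
#' deviation (divisor n - 1) is the default; the population form is
#' available via `sd_type`. Undefined for a zero mean (all-zero windows):
#' this is an error, not an infinity.
#'
#' @inheritParams rao_q
#' @param sd_type `"sample"` (n - 1, default) or `"population"` (n).
#' @return Non-negative coefficient of variation (unitless).
#' @export
coefficient_of_variation <- function(window,
                                     sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  x <- if (inherits(window, "plot_window")) window$heights else
    as.numeric(window)
  if (length(x) < 2L) stop("CV requires at least two pixels")
  m <- mean(x)
  if (m <= 0) stop("CV undefined: window mean height is not positive")
  s <- stats::sd(x)
  if (sd_type == "population") s <- s * sqrt((length(x) - 1) / length(x))
  s / m
}

# discrete height classes by rounding; the abundance basis of the
# Shannon/Simpson window indices
.height_classes <- function(x, round_digits) table(round(x, round_digits))

#' Shannon's H of a plot window (remote-sensing form)
#'
#' Heights are rounded to `round_digits` decimals to define discrete height
#' classes; Hrs = -sum(p_i log p_i) over the class relative abundances,
#' natural log. Depends only on class abundances, not on the height values
#' themselves.
#'
#' @inheritParams rao_q
#' @param round_digits decimals used to bin heights into classes (default
#'   1, i.e. 0.1 m classes).
#' @return Non-negative Shannon index.
#' @export
shannon_rs <- function(window, round_digits = 1) {
  x <- if (inherits(window, "plot_window")) window$heights else
    as.numeric(window)
  if (length(x) < 1L) stop("empty window")
  p <- as.numeric(.height_classes(x, round_digits))
  p <- p / sum(p)
  -sum(p * log(p))
}

#' Simpson's D of a plot window (remote-sensing form)
#'
#' D = sum(p_i^2) over height-class relative abundances (same rounding as
#' [shannon_rs()]). D = 1 for a constant window (minimum heterogeneity) and
#' 1/q for q equally abundant classes.
#'
#' @inheritParams shannon_rs
#' @return Simpson concentration in (0, 1].
#' @export
simpson_d <- function(window, round_digits = 1) {
  x <- if (inherits(window, "plot_window")) window$heights else
    as.numeric(window)
  if (length(x) < 1L) stop("empty window")
  p <- as.numeric(.height_classes(x, round_digits))
  p <- p / sum(p)
  sum(p^2)
}

#' Height-heterogeneity table for a set of plots
#'
#' Computes the four height-heterogeneity indices (Rao's Q, CV, Shannon's
#' H, Simpson's D) on every plot window of a CHM. Plots whose window cannot
#' be used (outside the grid, all nodata) are reported in the `rejects`
#' attribute rather than silently dropped; a window with zero mean height
#' yields `NA` for CV only.
#'
#' @param grid a [raster_grid()] CHM.
#' @param plots a `plot_geometry` data frame.
#' @param chm_source label recorded in the `chm_source` column.
#' @param round_digits height-class rounding for Shannon/Simpson.
#' @param distance Rao's Q distance mode.
#' @return Data frame with columns `plot_id`, `chm_source`, `rao_q`, `cv`,
#'   `shannon_rs`, `simpson_d`, `n_pixels`, `n_nodata`; rejected plots (with
#'   reasons) in `attr(, "rejects")`.
#' @export
plot_heterogeneity <- function(grid, plots, chm_source = "chm",
                               round_digits = 1,
                               distance = c("euclidean", "half_squared")) {
  distance <- match.arg(distance)
  rows <- list(); rejects <- list()
  for (i in seq_len(nrow(plots))) {
    p <- plots[i, ]
    w <- tryCatch(extract_plot_window(grid, p), error = function(e) e)
    if (inherits(w, "error")) {
      rejects[[length(rejects) + 1L]] <-
        data.frame(plot_id = as.character(p$plot_id),
                   reason = conditionMessage(w))
      next
    }
    cv <- tryCatch(coefficient_of_variation(w), error = function(e) NA_real_)
    rows[[length(rows) + 1L]] <- data.frame(
      plot_id = w$plot_id, chm_source = chm_source,
      rao_q = rao_q(w, distance), cv = cv,
      shannon_rs = shannon_rs(w, round_digits),
      simpson_d = simpson_d(w, round_digits),
      n_pixels = w$n_pixels, n_nodata = w$n_nodata)
  }
  if (length(rows) == 0L) stop("no usable plots")
  out <- do.call(rbind, rows)
  attr(out, "rejects") <- if (length(rejects)) do.call(rbind, rejects) else
    data.frame(plot_id = character(), reason = character())
  out
}

#' Moving-window Rao's Q map
#'
#' Slides a square window of `window_cells` x `window_cells` over the grid
#' and writes Rao's Q of the neighbourhood to its centre cell. Border cells
#' where the window would be incomplete are nodata (no partial windows, so
#' every output value is a full-window statistic). Nodata input cells are
#' excluded within each window; if fewer than 2 valid pixels remain the
#' output cell is nodata.
#'
#' @param grid a [raster_grid()].
#' @param window_cells odd integer >= 3, window edge in cells.
#' @param distance Rao's Q distance mode.
#' @return A [raster_grid()] with the same geometry as the input.
#' @export
rao_moving_window_map <- function(grid, window_cells = 3,
                                  distance = c("euclidean", "half_squared")) {
  distance <- match.arg(distance)
  w <- as.integer(window_cells)
  if (is.na(w) || w < 3L || w %% 2L == 0L)
    stop("`window_cells` must be an odd integer >= 3")
  v <- grid$values
  if (nrow(v) < w || ncol(v) < w) stop("window larger than grid")
  half <- w %/% 2L
  out <- matrix(NA_real_, nrow(v), ncol(v))
  for (r in (half + 1L):(nrow(v) - half)) {
    for (cc in (half + 1L):(ncol(v) - half)) {
      x <- v[(r - half):(r + half), (cc - half):(cc + half)]
      x <- x[!is.na(x)]
      if (length(x) >= 2L) out[r, cc] <- rao_q(x, distance)
    }
  }
  raster_grid(out, grid$cell_size, origin = grid$origin,
              nodata = grid$nodata, crs_id = grid$crs_id)
}
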
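# Independent oracles and fixture builders shared across the suite.

# Naive O(N^2) Rao's Q: explicit loop over ordered pixel pairs, inner loop
# vectorized. Independent of the production implementation.
rao_oracle <- function(x, distance = "euclidean") {
  n <- length(x)
  total <- 0
  for (i in seq_len(n)) {
    d <- if (distance == "euclidean") abs(x[i] - x) else (x[i] - x)^2 / 2
    total <- total + sum(d)
  }
  total / n^2
}

# random window of heights: mixture of integer-valued and fractional pixels
random_heights <- function(n) {
  h <- stats::runif(n, 0, 35)
  int <- stats::runif(n) < 0.5
  h[int] <- round(h[int])
  h
}

# wrap a bare height vector as a plot_window
as_window <- function(h, plot_id = "w", cell = 10, n_nodata = 0) {
  structure(list(plot_id = plot_id, heights = h, n_pixels = length(h),
                 n_nodata = n_nodata, source_cell_size = cell),
            class = "plot_window")
}

# grid whose 10 x 10 window over `plot100()` holds exactly the given heights
grid_from_heights <- function(h, nrow = 10, cell = 10) {
  raster_grid(matrix(h, nrow = nrow), cell,
              origin = c(0, nrow(matrix(h, nrow = nrow)) * cell))
}

plot100 <- function(id = "p1", e = 50, n = 50) plot_geometry(id, e, n, 100)

# tiny scene configuration for fast pipeline tests
small_scene_config <- function(seed = 1, coupling = 1, n_plots = 6)
  scene_config(n_plots = n_plots, coupling = coupling, seed = seed)

# inventory data frame from a named abundance vector
inventory_from_counts <- function(counts, plot_id = "p1", dbh = 20) {
  data.frame(plot_id = plot_id,
             species = rep(names(counts), counts),
             dbh_cm = dbh)
}
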
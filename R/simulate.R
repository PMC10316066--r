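#' Configuration for a synthetic forest scene
#'
#' Defines the study conditions the simulator emulates: 1 ha square plots,
#' a fine "truth" CHM at 2.5 m cells, coarser noisy product CHMs at 10 and
#' 30 m, stem densities in the range reported for temperate European
#' inventory plots (~650-1000 trees/ha), and product errors of a few metres.
#' The `coupling` knob sets how strongly plot-level vertical structural
#' complexity drives species diversity: at 1 the two are tied (the height
#' variation hypothesis holds by construction), at 0 they are independent
#' (an exact null).
#'
#' @param n_plots number of 1 ha plots (default 130).
#' @param plot_side plot edge in metres (default 100).
#' @param truth_cell truth CHM cell size in metres (default 2.5).
#' @param product_cells cell sizes of degraded product CHMs (default
#'   `c(10, 30)`).
#' @param species_pool number of species labels available (default 12).
#' @param coupling structure-diversity coupling strength in `[0, 1]`.
#' @param base_density expected stems per hectare (default 700).
#' @param height_layers maximum number of vertical strata (default 4; layer
#'   mean heights 6, 14, 22, 30 m).
#' @param noise_sd per-cell Gaussian noise of product CHMs, metres
#'   (default 3).
#' @param bias additive offset of product CHMs, metres (default +1,
#'   products tend to overestimate height slightly).
#' @param seed integer seed; every random draw in the scene derives from it.
#' @return A list of class `scene_config`.
#' @export
scene_config <- function(n_plots = 130, plot_side = 100, truth_cell = 2.5,
                         product_cells = c(10, 30), species_pool = 12,
                         coupling = 1, base_density = 700,
                         height_layers = 4, noise_sd = 3, bias = 1,
                         seed = 1) {
  if (coupling < 0 || coupling > 1) stop("`coupling` must be in [0, 1]")
  if (noise_sd < 0) stop("`noise_sd` must be non-negative")
  if (any(product_cells < truth_cell))
    stop("product cells must be at least the truth cell size")
  if (any(abs(product_cells / truth_cell -
              round(product_cells / truth_cell)) > 1e-9))
    stop("product cells must be integer multiples of the truth cell")
  structure(list(n_plots = as.integer(n_plots), plot_side = plot_side,
                 truth_cell = truth_cell, product_cells = product_cells,
                 species_pool = as.integer(species_pool),
                 coupling = coupling, base_density = base_density,
                 height_layers = as.integer(height_layers),
                 noise_sd = noise_sd, bias = bias, seed = as.integer(seed)),
            class = "scene_config")
}

# deterministic per-plot seed from (scene seed, plot index): order-independent
.plot_seed <- function(seed, i) {
  as.integer((as.double(seed) * 1000003 + as.double(i) * 7919) %% 2147483629) + 1L
}

# run expr under a local RNG state seeded with `seed`
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
    assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

#' Simulate the trees of one field plot
#'
#' Draws a latent structural complexity c ~ Uniform(0, 1) (overridable via
#' `complexity`). The plot occupies L = 1 + round(c * (height_layers - 1))
#' vertical strata with mean top heights 6, 14, 22, 30 m. With probability
#' `coupling` the realized species count q is tied to c
#' (q = 1 + Binomial(species_pool - 1, c)) and species evenness increases
#' with c; otherwise q and evenness are drawn independently of c — so
#' coupling = 0 gives exact independence between vertical structure and
#' diversity, and coupling = 1 a monotone dependence. Trees are placed
#' uniformly in the plot, stems get layer heights plus jitter, crowns are
#' flat-topped disks with radius 0.15 * height + 0.5 m, and every stem has
#' DBH >= 5 cm (all trees pass the census filter).
#'
#' @param config a [scene_config()].
#' @param plot one-row [plot_geometry()].
#' @param seed integer seed for this plot's private stream.
#' @param complexity optional fixed latent complexity in `[0, 1]` (for
#'   corner-case studies); if `NULL` it is drawn.
#' @return List with `inventory` (data frame: plot_id, species, dbh_cm, x,
#'   y, height_m), `crowns` (data frame: x, y, height, radius), and the
#'   latent `complexity`, `layers`, `q`.
#' @export
simulate_stand <- function(config, plot, seed, complexity = NULL) {
  .with_seed(seed, {
    c_lat <- if (is.null(complexity)) stats::runif(1) else complexity
    L <- 1L + as.integer(round(c_lat * (config$height_layers - 1L)))
    coupled <- stats::runif(1) < config$coupling
    if (coupled) {
      q <- 1L + stats::rbinom(1L, config$species_pool - 1L, c_lat)
      even <- c_lat
    } else {
      q <- sample.int(config$species_pool, 1L)
      even <- stats::runif(1)
    }
    area_ha <- (plot$side / 100)^2
    n <- stats::rpois(1L, config$base_density * area_ha)
    layer_means <- seq(6, by = 8, length.out = config$height_layers)
    if (n == 0L) {
      inv <- data.frame(plot_id = character(), species = character(),
                        dbh_cm = numeric(), x = numeric(), y = numeric(),
                        height_m = numeric())
      crowns <- data.frame(x = numeric(), y = numeric(), height = numeric(),
                           radius = numeric())
      return(list(inventory = inv, crowns = crowns, complexity = c_lat,
                  layers = L, q = q))
    }
    layer <- sample.int(L, n, replace = TRUE)
    height <- pmax(2.5, layer_means[layer] + stats::rnorm(n, sd = 1.5))
    dbh <- pmax(5, 1.8 * height + stats::rnorm(n, sd = 2))
    # geometric-series abundances; ratio -> 1 (even) as `even` -> 1
    ratio <- 0.35 + 0.65 * even
    sp_ids <- sample.int(config$species_pool, q)
    pr <- ratio^(seq_len(q) - 1); pr <- pr / sum(pr)
    species <- sprintf("sp%02d", sp_ids[sample.int(q, n, replace = TRUE,
                                                   prob = pr)])
    x <- plot$center_e + stats::runif(n, -plot$side / 2, plot$side / 2)
    y <- plot$center_n + stats::runif(n, -plot$side / 2, plot$side / 2)
    list(inventory = data.frame(plot_id = as.character(plot$plot_id),
                                species = species, dbh_cm = dbh, x = x,
                                y = y, height_m = height),
         crowns = data.frame(x = x, y = y, height = height,
                             radius = 0.15 * height + 0.5),
         complexity = c_lat, layers = L, q = q)
  })
}

#' Rasterize crown disks to a canopy height model
#'
#' Each cell of a grid covering the plot square takes the maximum crown-top
#' height among the crown disks covering its centre; cells under no crown
#' are bare ground at 0 m (not nodata, so canopy-cover logic sees them).
#'
#' @param crowns data frame with `x`, `y`, `height`, `radius` (metres).
#' @param plot one-row [plot_geometry()].
#' @param cell output cell size in metres.
#' @return A [raster_grid()] covering the plot square.
#' @export
rasterize_chm <- function(crowns, plot, cell) {
  if (cell <= 0) stop("`cell` must be positive")
  n_cells <- as.integer(ceiling(plot$side / cell - 1e-9))
  ox <- plot$center_e - plot$side / 2
  oy <- plot$center_n + plot$side / 2
  v <- matrix(0, n_cells, n_cells)
  if (nrow(crowns) > 0L) {
    cx <- ox + (seq_len(n_cells) - 0.5) * cell       # column centres (E)
    cy <- oy - (seq_len(n_cells) - 0.5) * cell       # row centres (N)
    for (t in seq_len(nrow(crowns))) {
      r <- crowns$radius[t]
      jj <- which(abs(cx - crowns$x[t]) <= r)
      ii <- which(abs(cy - crowns$y[t]) <= r)
      if (!length(jj) || !length(ii)) next
      dx2 <- (cx[jj] - crowns$x[t])^2
      dy2 <- (cy[ii] - crowns$y[t])^2
      hit <- outer(dy2, dx2, `+`) <= r^2
      blk <- v[ii, jj, drop = FALSE]
      blk[hit] <- pmax(blk[hit], crowns$height[t])
      v[ii, jj] <- blk
    }
  }
  raster_grid(v, cell, origin = c(ox, oy))
}

#' Degrade a truth CHM into a coarser, noisy product CHM
#'
#' Aggregates (mean) to the target cell size, adds a constant bias and
#' i.i.d. Gaussian noise, and clamps at 0 — emulating the few-metre errors
#' of satellite-derived CHM products relative to airborne-laser references.
#'
#' @param grid truth [raster_grid()].
#' @param bias additive offset in metres.
#' @param noise_sd per-cell Gaussian noise SD in metres.
#' @param target_cell output cell size (integer multiple of the input's).
#' @param seed integer seed for the noise stream.
#' @return A degraded [raster_grid()].
#' @export
degrade_chm <- function(grid, bias, noise_sd, target_cell, seed) {
  f <- target_cell / grid$cell_size
  if (f < 1 - 1e-9) stop("`target_cell` smaller than the source cell")
  if (abs(f - round(f)) > 1e-9)
    stop("`target_cell` must be an integer multiple of the source cell")
  f <- as.integer(round(f))
  g <- if (f > 1L) aggregate_raster(grid, f, "mean") else grid
  .with_seed(seed, {
    v <- g$values + bias
    if (noise_sd > 0)
      v <- v + matrix(stats::rnorm(length(v), sd = noise_sd), nrow(v))
    v[!is.na(v) & v < 0] <- 0
    v[is.na(g$values)] <- NA_real_
    raster_grid(v, g$cell_size, origin = g$origin, nodata = g$nodata,
                crs_id = g$crs_id)
  })
}

# smallest multiple of m that is >= x
.round_up <- function(x, m) as.integer(ceiling(x / m) * m)

#' Simulate a complete forest scene
#'
#' Lays the plots out as a contiguous mosaic of 1 ha squares, simulates a
#' stand per plot (each from its own seed stream derived from the scene
#' seed and plot index, so regeneration is order-independent), rasterizes
#' the truth CHM, and degrades it to each product cell size. The mosaic is
#' padded with bare ground so every product cell size divides the scene
#' evenly. With `out_dir` given, writes `truth_chm.asc`,
#' `product_<cell>m.asc`, `plots.csv`, `inventory.csv` and `manifest.json`
#' (config, seed, file checksums); the manifest suffices to regenerate the
#' bundle bit-identically.
#'
#' @param config a [scene_config()].
#' @param out_dir optional output directory.
#' @return A `scene_bundle`: list with `config`, `plots`, `inventory`,
#'   `truth_chm`, `product_chms` (named by cell size), `stand_info` (latent
#'   per-plot complexity, layers, species count), and `manifest`.
#' @export
simulate_scene <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "scene_config"))
  plot_cells <- config$plot_side / config$truth_cell
  if (abs(plot_cells - round(plot_cells)) > 1e-9)
    stop("truth cell must divide the plot side")
  plot_cells <- as.integer(round(plot_cells))
  # mosaic dimensions in plots, padded so every product factor divides the
  # scene dimension in truth cells
  factors <- as.integer(round(config$product_cells / config$truth_cell))
  need <- 1L
  for (f in factors) {
    m <- f %/% .gcd(f, plot_cells)
    need <- .lcm(need, m)
  }
  np_col <- .round_up(ceiling(sqrt(config$n_plots)), need)
  np_row <- .round_up(ceiling(config$n_plots / np_col), need)
  side <- config$plot_side
  centers <- expand.grid(col = seq_len(np_col), row = seq_len(np_row))
  centers <- centers[order(centers$row, centers$col), ]
  plots <- plot_geometry(
    sprintf("plot%03d", seq_len(config$n_plots)),
    center_e = (centers$col[seq_len(config$n_plots)] - 0.5) * side,
    center_n = (np_row - centers$row[seq_len(config$n_plots)] + 0.5) * side,
    side = side)
  scene_rows <- np_row * plot_cells
  scene_cols <- np_col * plot_cells
  truth <- matrix(0, scene_rows, scene_cols)
  invs <- list(); info <- list()
  for (i in seq_len(config$n_plots)) {
    p <- plots[i, ]
    st <- simulate_stand(config, p, seed = .plot_seed(config$seed, i))
    invs[[i]] <- st$inventory
    info[[i]] <- data.frame(plot_id = p$plot_id, complexity = st$complexity,
                            layers = st$layers, q = st$q)
    block <- rasterize_chm(st$crowns, p, config$truth_cell)
    r0 <- (centers$row[i] - 1L) * plot_cells
    c0 <- (centers$col[i] - 1L) * plot_cells
    truth[r0 + seq_len(plot_cells), c0 + seq_len(plot_cells)] <- block$values
  }
  truth_chm <- raster_grid(truth, config$truth_cell,
                           origin = c(0, np_row * side))
  products <- list()
  for (j in seq_along(config$product_cells)) {
    pc <- config$product_cells[j]
    products[[sprintf("%gm", pc)]] <- degrade_chm(
      truth_chm, bias = config$bias, noise_sd = config$noise_sd,
      target_cell = pc, seed = .plot_seed(config$seed, 10^6 + j))
  }
  inventory <- do.call(rbind, invs)
  bundle <- structure(
    list(config = config, plots = plots, inventory = inventory,
         truth_chm = truth_chm, product_chms = products,
         stand_info = do.call(rbind, info), manifest = NULL),
    class = "scene_bundle")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(truth_chm = file.path(out_dir, "truth_chm.asc"),
               plots = file.path(out_dir, "plots.csv"),
               inventory = file.path(out_dir, "inventory.csv"))
    write_raster(truth_chm, paths[["truth_chm"]])
    write_plots(plots, paths[["plots"]])
    utils::write.csv(inventory, paths[["inventory"]], row.names = FALSE,
                     quote = FALSE)
    for (nm in names(products)) {
      paths[[paste0("product_", nm)]] <-
        file.path(out_dir, sprintf("product_%s.asc", nm))
      write_raster(products[[nm]], paths[[paste0("product_", nm)]])
    }
    manifest <- list(config = unclass(config), seed = config$seed,
                     files = stats::setNames(as.list(basename(paths)),
                                             names(paths)),
                     md5 = as.list(unname(tools::md5sum(paths))))
    names(manifest$md5) <- names(paths)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    bundle$manifest <- manifest
  }
  bundle
}

.gcd <- function(a, b) if (b == 0L) a else .gcd(b, a %% b)
.lcm <- function(a, b) a %/% .gcd(a, b) * b

#' @export
print.scene_bundle <- function(x, ...) {
  cat(sprintf("scene_bundle: %d plots of %g m, truth CHM %d x %d @ %g m\n",
              nrow(x$plots), x$config$plot_side, nrow(x$truth_chm$values),
              ncol(x$truth_chm$values), x$config$truth_cell))
  cat(sprintf("  %d trees, %d species; products: %s; coupling = %g, seed = %d\n",
              nrow(x$inventory), length(unique(x$inventory$species)),
              paste(names(x$product_chms), collapse = ", "),
              x$config$coupling, x$config$seed))
  invisible(x)
}
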
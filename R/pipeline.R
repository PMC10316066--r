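#' Build a pipeline run configuration
#'
#' A run configuration names the inputs (either a simulated scene directory
#' containing `manifest.json`, or explicit raster/CSV paths) and the
#' analysis settings. It can also be read from a YAML or JSON file with the
#' same field names via [read_run_config()].
#'
#' @param out_dir output directory for all tables, reports and logs.
#' @param scene_dir directory written by [simulate_scene()]; mutually
#'   exclusive with the explicit paths.
#' @param truth_chm,plots,inventory explicit input paths (ESRI ASCII grid /
#'   CSV); `truth_chm` doubles as the validation reference.
#' @param product_chms named character vector of product raster paths
#'   (names are the source labels, e.g. `c("10m" = "prod10.asc")`).
#' @param responses diversity responses to regress
#'   (subset of `shannon_h`, `richness`).
#' @param round_digits height-class rounding for Shannon/Simpson indices.
#' @param cc_threshold canopy-cover height threshold (metres).
#' @param min_dbh census DBH threshold (cm).
#' @param cv_k,cv_repeats,cv_seed repeated k-fold settings.
#' @param headline_index index used for the cross-validated models
#'   (default `rao_q`).
#' @param rao_map_window odd window size for the moving-window Rao's Q map
#'   of the headline product, or `NULL` to skip the map.
#' @return A list of class `run_config`.
#' @export
run_config <- function(out_dir, scene_dir = NULL, truth_chm = NULL,
                       plots = NULL, inventory = NULL, product_chms = NULL,
                       responses = c("shannon_h", "richness"),
                       round_digits = 1, cc_threshold = 2, min_dbh = 5,
                       cv_k = 10, cv_repeats = 3, cv_seed = 1,
                       headline_index = "rao_q", rao_map_window = NULL) {
  structure(list(out_dir = out_dir, scene_dir = scene_dir,
                 truth_chm = truth_chm, plots = plots, inventory = inventory,
                 product_chms = product_chms, responses = responses,
                 round_digits = round_digits, cc_threshold = cc_threshold,
                 min_dbh = min_dbh, cv_k = cv_k, cv_repeats = cv_repeats,
                 cv_seed = cv_seed, headline_index = headline_index,
                 rao_map_window = rao_map_window),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML (`.yml`/`.yaml`) or JSON configuration file.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path) else jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(cfg$out_dir)) stop("config must set `out_dir`")
  if (!is.null(cfg$product_chms)) cfg$product_chms <- unlist(cfg$product_chms)
  do.call(run_config, cfg)
}

# resolve a run_config into in-memory inputs
.load_inputs <- function(config) {
  if (!is.null(config$scene_dir)) {
    man_path <- file.path(config$scene_dir, "manifest.json")
    if (!file.exists(man_path))
      stop("scene_dir has no manifest.json: ", config$scene_dir)
    man <- jsonlite::read_json(man_path, simplifyVector = TRUE)
    f <- function(key) file.path(config$scene_dir, man$files[[key]])
    prods <- grep("^product_", names(man$files), value = TRUE)
    products <- lapply(prods, function(k) read_raster(f(k)))
    names(products) <- sub("^product_", "", prods)
    list(truth = read_raster(f("truth_chm")),
         plots = read_plots(f("plots")),
         inventory = read_inventory(f("inventory")),
         products = products,
         input_paths = vapply(c("truth_chm", "plots", "inventory", prods),
                              f, character(1)))
  } else {
    for (fld in c("plots", "inventory", "product_chms"))
      if (is.null(config[[fld]])) stop("config missing `", fld, "`")
    products <- lapply(config$product_chms, read_raster)
    names(products) <- names(config$product_chms)
    list(truth = if (is.null(config$truth_chm)) NULL else
           read_raster(config$truth_chm),
         plots = read_plots(config$plots),
         inventory = read_inventory(config$inventory),
         products = products,
         input_paths = c(config$truth_chm, config$plots, config$inventory,
                         unname(config$product_chms)))
  }
}

.fail <- function(out_dir, stage, err) {
  writeLines(c(stage, conditionMessage(err)),
             file.path(out_dir, "FAILED"))
  stop(sprintf("pipeline stage '%s' failed: %s", stage,
               conditionMessage(err)), call. = FALSE)
}

.stage <- function(out_dir, name, expr) {
  tryCatch(expr, error = function(e) .fail(out_dir, name, e))
}

#' Run the full height-variation-hypothesis workflow
#'
#' Executes, in order: CHM validation against the reference (skipped when
#' no reference CHM is available), per-plot field diversity, canopy cover
#' and stem density, the four height-heterogeneity indices on every product
#' CHM, single linear regressions for every (index x response x product)
#' combination, repeated k-fold cross-validation of the headline single and
#' multiple models, the inter-index R-squared matrix, and optionally a
#' moving-window Rao's Q map. All tables are written as CSV, reports as
#' JSON, plus a machine-readable `summary.json`; outputs are pure functions
#' of (inputs, config, seeds), so a rerun with the same configuration is
#' byte-identical. A stage failure aborts the run, names the stage, and
#' leaves partial outputs with a `FAILED` marker.
#'
#' @param config a [run_config()], or the path of a YAML/JSON config file.
#' @return The output directory path, invisibly; the parsed summary as the
#'   `summary` attribute.
#' @export
run_hvh <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  unlink(file.path(out, "FAILED"))
  jsonlite::write_json(unclass(config), file.path(out, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  inp <- .stage(out, "load_inputs", .load_inputs(config))
  summary <- list(stages = list())

  # 1. validation of each product against the reference, matched cell size
  validation <- NULL
  if (!is.null(inp$truth)) {
    validation <- .stage(out, "validation", {
      rows <- lapply(names(inp$products), function(nm) {
        prod <- inp$products[[nm]]
        f <- as.integer(round(prod$cell_size / inp$truth$cell_size))
        ref <- if (f > 1L) aggregate_raster(inp$truth, f, "mean") else
          inp$truth
        v <- validate_chm(prod, ref, inp$plots)
        data.frame(chm_source = nm, r_squared = v$r_squared,
                   p_value = v$p_value, rmse_m = v$rmse, mae_m = v$mae,
                   bias_m = v$bias, n_pixels = v$n)
      })
      do.call(rbind, rows)
    })
    utils::write.csv(validation, file.path(out, "validation.csv"),
                     row.names = FALSE, quote = FALSE)
    summary$stages$validation <- "done"
  } else {
    summary$stages$validation <- "skipped (no reference CHM)"
  }

  # 2. field diversity, canopy cover, density
  div <- .stage(out, "diversity",
                diversity_table(inp$inventory, min_dbh = config$min_dbh))
  utils::write.csv(div, file.path(out, "diversity.csv"), row.names = FALSE,
                   quote = FALSE)
  cover <- .stage(out, "canopy_cover", {
    grid <- if (!is.null(inp$truth)) inp$truth else
      inp$products[[which.min(vapply(inp$products, `[[`, 0, "cell_size"))]]
    canopy_cover_table(grid, inp$plots, threshold = config$cc_threshold)
  })
  utils::write.csv(cover, file.path(out, "canopy_cover.csv"),
                   row.names = FALSE, quote = FALSE)
  summary$stages$diversity <- "done"

  # 3. heterogeneity per product CHM
  het <- .stage(out, "heterogeneity", {
    tabs <- lapply(names(inp$products), function(nm)
      plot_heterogeneity(inp$products[[nm]], inp$plots, chm_source = nm,
                         round_digits = config$round_digits))
    do.call(rbind, tabs)
  })
  utils::write.csv(het, file.path(out, "heterogeneity.csv"),
                   row.names = FALSE, quote = FALSE)
  summary$stages$heterogeneity <- "done"

  indices <- c("rao_q", "cv", "shannon_rs", "simpson_d")

  # 4. single regressions: index x response x product
  reg <- .stage(out, "regressions", {
    rows <- list()
    for (nm in names(inp$products)) {
      h <- het[het$chm_source == nm, ]
      m <- merge(h, div, by = "plot_id")
      for (ix in indices) for (resp in config$responses) {
        ok <- stats::complete.cases(m[, c(ix, resp)])
        fit <- fit_linear(m[[ix]][ok], m[[resp]][ok], xname = ix,
                          yname = resp)
        rows[[length(rows) + 1L]] <- data.frame(
          chm_source = nm, index = ix, response = resp,
          r_squared = fit$r_squared, p_value = fit$p_value,
          rmse = fit$rmse, mae = fit$mae,
          slope = unname(fit$coefficients[2L]),
          intercept = unname(fit$coefficients[1L]), n = fit$n)
      }
    }
    do.call(rbind, rows)
  })
  utils::write.csv(reg, file.path(out, "regressions.csv"),
                   row.names = FALSE, quote = FALSE)
  summary$stages$regressions <- "done"

  # 5. cross-validated headline models (single and multiple)
  headline_src <- names(inp$products)[1L]
  cvres <- .stage(out, "cross_validation", {
    h <- het[het$chm_source == headline_src, ]
    m <- merge(merge(h, div, by = "plot_id"), cover, by = "plot_id")
    reports <- list()
    for (resp in config$responses) {
      ok <- stats::complete.cases(
        m[, c(config$headline_index, "canopy_cover_pct", "n_trees", resp)])
      mm <- m[ok, ]
      single <- repeated_kfold_cv(mm[[config$headline_index]], mm[[resp]],
                                  k = config$cv_k,
                                  repeats = config$cv_repeats,
                                  seed = config$cv_seed)
      multi <- repeated_kfold_cv(
        data.frame(hh = mm[[config$headline_index]],
                   canopy_cover = mm$canopy_cover_pct,
                   density = mm$n_trees),
        mm[[resp]], k = config$cv_k, repeats = config$cv_repeats,
        seed = config$cv_seed)
      reports[[resp]] <- list(single = single, multiple = multi)
    }
    reports
  })
  cv_rows <- list()
  for (resp in names(cvres)) for (kind in c("single", "multiple")) {
    cv <- cvres[[resp]][[kind]]
    cv_rows[[length(cv_rows) + 1L]] <- data.frame(
      chm_source = headline_src, index = config$headline_index,
      response = resp, model = kind, k = cv$k, repeats = cv$repeats,
      seed = cv$seed, mean_r2 = cv$mean_r2, mean_rmse = cv$mean_rmse,
      mean_mae = cv$mean_mae, pooled_r2 = cv$pooled_r2,
      pooled_rmse = cv$pooled_rmse, pooled_mae = cv$pooled_mae)
  }
  cv_tab <- do.call(rbind, cv_rows)
  utils::write.csv(cv_tab, file.path(out, "cross_validation.csv"),
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    lapply(cvres, function(r) lapply(r, function(cv)
      list(k = cv$k, repeats = cv$repeats, seed = cv$seed,
           mean_r2 = cv$mean_r2, mean_rmse = cv$mean_rmse,
           mean_mae = cv$mean_mae, per_fold = cv$per_fold))),
    file.path(out, "cv_reports.json"), auto_unbox = TRUE, pretty = TRUE,
    digits = NA)
  summary$stages$cross_validation <- "done"

  # 6. inter-index R2 matrix on the headline product
  mat <- .stage(out, "index_correlation",
                index_correlation_matrix(het[het$chm_source == headline_src, ]))
  utils::write.csv(data.frame(index = rownames(mat), mat),
                   file.path(out, "index_r2_matrix.csv"), row.names = FALSE,
                   quote = FALSE)
  summary$stages$index_correlation <- "done"

  # 7. optional moving-window Rao's Q map of the headline product
  if (!is.null(config$rao_map_window)) {
    .stage(out, "rao_map", {
      map <- rao_moving_window_map(inp$products[[headline_src]],
                                   window_cells = config$rao_map_window)
      write_raster(map, file.path(out, "rao_map.asc"))
    })
    summary$stages$rao_map <- "done"
  } else {
    summary$stages$rao_map <- "skipped"
  }

  headline <- cv_tab[cv_tab$response == config$responses[1L] &
                       cv_tab$model == "single", ]
  summary$headline <- list(
    chm_source = headline_src, index = config$headline_index,
    response = config$responses[1L], mean_r2 = headline$mean_r2,
    mean_rmse = headline$mean_rmse, mean_mae = headline$mean_mae)
  summary$seeds <- list(cv_seed = config$cv_seed)
  summary$n_plots <- nrow(inp$plots)
  summary$inputs_md5 <- as.list(tools::md5sum(inp$input_paths))
  if (!is.null(validation))
    summary$validation <- split(validation, seq_len(nrow(validation)))
  jsonlite::write_json(summary, file.path(out, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(structure(out, summary = summary))
}
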
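#' Root mean square error between two value series
#'
#' RMSE = sqrt(mean((x - y)^2)). For CHM validation, `x` is the product
#' under test and `y` the reference, element-wise over matched pixels.
#'
#' @param x,y numeric vectors of equal length >= 1.
#' @return Non-negative RMSE in the units of the inputs.
#' @export
rmse <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 1L) stop("empty input")
  sqrt(mean((x - y)^2))
}

#' Mean absolute error between two value series
#'
#' MAE = mean(|x - y|). Always <= RMSE (power-mean inequality), with
#' equality iff all residuals share one magnitude.
#'
#' @inheritParams rmse
#' @return Non-negative MAE in the units of the inputs.
#' @export
mae <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 1L) stop("empty input")
  mean(abs(x - y))
}

# assemble an hvh_fit from an lm and its data
.hvh_fit <- function(fit, response, predictors, n) {
  sm <- summary(fit)
  fstat <- sm$fstatistic
  p_overall <- if (is.null(fstat)) NA_real_ else
    unname(stats::pf(fstat[1L], fstat[2L], fstat[3L], lower.tail = FALSE))
  y <- stats::model.response(stats::model.frame(fit))
  yhat <- stats::fitted(fit)
  structure(
    list(fit = fit, response = response, predictors = predictors,
         coefficients = stats::coef(fit), r_squared = sm$r.squared,
         p_value = p_overall, rmse = rmse(yhat, y), mae = mae(yhat, y),
         n = n),
    class = "hvh_fit")
}

#' Fit a simple linear regression of diversity on heterogeneity
#'
#' Ordinary least squares of `y` on a single predictor `x`. R-squared is
#' the squared Pearson correlation; the p-value is the slope's t-test
#' (equivalently the overall F on 1 df); RMSE/MAE are computed on fitted
#' versus observed values.
#'
#' @param x numeric predictor (e.g. a height-heterogeneity index).
#' @param y numeric response (e.g. Shannon's H or species richness).
#' @param xname,yname labels recorded in the report.
#' @return An object of class `hvh_fit` with `print`, `summary`, `coef`,
#'   `predict`, `residuals` and `plot` methods.
#' @export
fit_linear <- function(x, y, xname = "hh", yname = "diversity") {
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (stats::var(x) == 0) stop("predictor has zero variance")
  d <- data.frame(y = y, x = x)
  fit <- stats::lm(y ~ x, data = d)
  .hvh_fit(fit, yname, xname, length(y))
}

#' Fit a multiple linear regression of diversity on structure covariates
#'
#' OLS of `y` on all columns of `predictors` plus an intercept — the
#' standard extension adding canopy cover and stem density to the
#' heterogeneity index. A rank-deficient (collinear) design, including
#' duplicated columns, is an error.
#'
#' @param predictors data frame of numeric predictor columns (e.g. `hh`,
#'   `canopy_cover`, `density`).
#' @param y numeric response.
#' @param yname response label.
#' @return An object of class `hvh_fit`.
#' @export
fit_multiple <- function(predictors, y, yname = "diversity") {
  predictors <- as.data.frame(predictors)
  if (nrow(predictors) != length(y)) stop("length mismatch")
  if (length(y) <= ncol(predictors) + 1L)
    stop("need more observations than coefficients")
  d <- cbind(data.frame(y = y), predictors)
  fit <- stats::lm(y ~ ., data = d)
  if (anyNA(stats::coef(fit)))
    stop("collinear design: predictors are linearly dependent")
  .hvh_fit(fit, yname, names(predictors), length(y))
}

#' @export
print.hvh_fit <- function(x, ...) {
  cat(sprintf("hvh_fit: %s ~ %s  (n = %d)\n", x$response,
              paste(x$predictors, collapse = " + "), x$n))
  cat(sprintf("  R2 = %.3f, p = %.3g, RMSE = %.3g, MAE = %.3g\n",
              x$r_squared, x$p_value, x$rmse, x$mae))
  cat("  coefficients:\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
summary.hvh_fit <- function(object, ...) summary(object$fit, ...)

#' @export
coef.hvh_fit <- function(object, ...) object$coefficients

#' @export
predict.hvh_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(stats::fitted(object$fit))
  if (is.numeric(newdata) && length(object$predictors) == 1L)
    newdata <- stats::setNames(data.frame(newdata), "x")
  stats::predict(object$fit, newdata = newdata, ...)
}

#' @export
residuals.hvh_fit <- function(object, ...) stats::residuals(object$fit, ...)

#' @export
plot.hvh_fit <- function(x, ...) {
  mf <- stats::model.frame(x$fit)
  if (ncol(mf) == 2L) {
    graphics::plot(mf[[2L]], mf[[1L]], xlab = x$predictors,
                   ylab = x$response,
                   main = sprintf("R2 = %.2f, p = %.2g", x$r_squared,
                                  x$p_value), ...)
    graphics::abline(x$fit, col = "red3", lwd = 2)
  } else {
    graphics::plot(stats::fitted(x$fit), mf[[1L]], xlab = "fitted",
                   ylab = x$response,
                   main = sprintf("R2 = %.2f", x$r_squared), ...)
    graphics::abline(0, 1, col = "red3", lwd = 2)
  }
  invisible(x)
}

#' Validate a CHM product against a reference CHM over field plots
#'
#' Pools matched pixel pairs (valid in both grids) across all plot windows
#' and reports the linear-fit R-squared, RMSE, MAE and mean error (bias,
#' product minus reference). Both grids must share the cell size and align
#' over the plots. With `mode = "plot_mean"` the per-plot mean heights are
#' compared instead of pooled pixels.
#'
#' @param product [raster_grid()] under test (e.g. a satellite CHM).
#' @param reference [raster_grid()] reference (e.g. an airborne-laser CHM).
#' @param plots a `plot_geometry` data frame.
#' @param mode `"pixel"` (default) or `"plot_mean"`.
#' @return An `hvh_validation`: list with `r_squared`, `p_value`, `rmse`,
#'   `mae`, `bias` and `n` (matched pairs).
#' @export
validate_chm <- function(product, reference, plots,
                         mode = c("pixel", "plot_mean")) {
  mode <- match.arg(mode)
  if (product$cell_size != reference$cell_size)
    stop("product and reference cell sizes differ")
  xs <- c(); ys <- c()
  for (i in seq_len(nrow(plots))) {
    p <- plots[i, ]
    mp <- .window_matrix(product, p)
    mr <- .window_matrix(reference, p)
    if (!identical(dim(mp), dim(mr)))
      stop(sprintf("plot '%s': windows misaligned between grids", p$plot_id))
    ok <- !is.na(mp) & !is.na(mr)
    if (mode == "pixel") {
      xs <- c(xs, mp[ok]); ys <- c(ys, mr[ok])
    } else if (any(ok)) {
      xs <- c(xs, mean(mp[ok])); ys <- c(ys, mean(mr[ok]))
    }
  }
  if (length(xs) == 0L) stop("zero matched pixel pairs")
  fit <- if (stats::var(ys) > 0 && stats::var(xs) > 0 && length(xs) >= 3L)
    fit_linear(ys, xs, xname = "reference", yname = "product") else NULL
  structure(
    list(r_squared = if (is.null(fit)) NA_real_ else fit$r_squared,
         p_value = if (is.null(fit)) NA_real_ else fit$p_value,
         rmse = rmse(xs, ys), mae = mae(xs, ys), bias = mean(xs - ys),
         n = length(xs), mode = mode),
    class = "hvh_validation")
}

#' @export
print.hvh_validation <- function(x, ...) {
  cat(sprintf(
    "CHM validation (%s, n = %d): R2 = %.3f, RMSE = %.3g m, MAE = %.3g m, bias = %+.3g m\n",
    x$mode, x$n, x$r_squared, x$rmse, x$mae, x$bias))
  invisible(x)
}

#' Repeated k-fold cross-validation of a linear regression
#'
#' For each repeat, observations are shuffled with the seeded generator and
#' split into `k` near-equal folds; each fold is held out once while an OLS
#' model is fitted on the rest. Per-fold R-squared is the squared Pearson
#' correlation of observed and predicted held-out values (the resampling
#' convention); RMSE and MAE are computed on held-out residuals. A fold
#' whose observed values have zero variance is skipped with a warning.
#' Means over all k * repeats folds are the headline metrics; the
#' variance-explained convention (1 - SSE/SST on held-out values) is
#' reported alongside as `*_r2_sst`, and metrics on the pooled held-out
#' predictions under `pooled_*`. The correlation convention carries a small
#' positive small-sample bias per fold, so only the SST convention is
#' guaranteed to sit below the training R-squared on average.
#'
#' @param predictors numeric vector or data frame of predictor columns.
#' @param y numeric response.
#' @param k number of folds (default 10).
#' @param repeats number of repeats (default 3).
#' @param seed integer seed; mandatory, recorded in the report.
#' @return An `hvh_cv`: list with `k`, `repeats`, `seed`, `per_fold` (data
#'   frame of fold metrics), `mean_r2`, `mean_rmse`, `mean_mae`, and
#'   `pooled_r2`, `pooled_rmse`, `pooled_mae`.
#' @export
repeated_kfold_cv <- function(predictors, y, k = 10, repeats = 3, seed) {
  if (missing(seed)) stop("`seed` is required")
  if (is.numeric(predictors) && is.null(dim(predictors)))
    predictors <- data.frame(x = predictors)
  predictors <- as.data.frame(predictors)
  n <- length(y)
  if (nrow(predictors) != n) stop("length mismatch")
  if (n < 2L * k) stop("need at least 2k observations")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
    globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  d <- cbind(data.frame(.y = y), predictors)
  per <- list(); pooled_obs <- c(); pooled_pred <- c()
  for (r in seq_len(repeats)) {
    idx <- sample.int(n)
    fold <- integer(n); fold[idx] <- rep(seq_len(k), length.out = n)
    for (f in seq_len(k)) {
      test <- which(fold == f)
      fit <- stats::lm(.y ~ ., data = d[-test, , drop = FALSE])
      pred <- stats::predict(fit, newdata = d[test, , drop = FALSE])
      obs <- y[test]
      if (stats::var(obs) == 0) {
        warning(sprintf("repeat %d fold %d skipped: zero variance in observed",
                        r, f))
        next
      }
      per[[length(per) + 1L]] <- data.frame(
        repeat_ = r, fold = f,
        r_squared = stats::cor(obs, pred)^2,
        r_squared_sst = 1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2),
        rmse = rmse(pred, obs), mae = mae(pred, obs), n_test = length(test))
      pooled_obs <- c(pooled_obs, obs); pooled_pred <- c(pooled_pred, pred)
    }
  }
  if (length(per) == 0L) stop("all folds skipped")
  pf <- do.call(rbind, per)
  structure(
    list(k = k, repeats = repeats, seed = as.integer(seed), per_fold = pf,
         mean_r2 = mean(pf$r_squared), mean_rmse = mean(pf$rmse),
         mean_mae = mean(pf$mae), mean_r2_sst = mean(pf$r_squared_sst),
         pooled_r2 = stats::cor(pooled_obs, pooled_pred)^2,
         pooled_r2_sst = 1 - sum((pooled_obs - pooled_pred)^2) /
           sum((pooled_obs - mean(pooled_obs))^2),
         pooled_rmse = rmse(pooled_pred, pooled_obs),
         pooled_mae = mae(pooled_pred, pooled_obs)),
    class = "hvh_cv")
}

#' @export
print.hvh_cv <- function(x, ...) {
  cat(sprintf("repeated k-fold CV: k = %d, repeats = %d, seed = %d (%d folds)\n",
              x$k, x$repeats, x$seed, nrow(x$per_fold)))
  cat(sprintf("  fold means : R2 = %.3f, RMSE = %.3g, MAE = %.3g\n",
              x$mean_r2, x$mean_rmse, x$mean_mae))
  cat(sprintf("  pooled     : R2 = %.3f, RMSE = %.3g, MAE = %.3g\n",
              x$pooled_r2, x$pooled_rmse, x$pooled_mae))
  invisible(x)
}

#' @export
summary.hvh_cv <- function(object, ...) {
  print(object)
  invisible(object$per_fold)
}

#' Pairwise R-squared matrix between heterogeneity indices
#'
#' Symmetric matrix of squared Pearson correlations between the four
#' height-heterogeneity index columns of a heterogeneity table, diagonal
#' exactly 1. Rao's Q and CV typically correlate strongly with each other
#' but weakly with the abundance-only Shannon/Simpson pair.
#'
#' @param table data frame with columns `rao_q`, `cv`, `shannon_rs`,
#'   `simpson_d` (one row per plot, e.g. from [plot_heterogeneity()]).
#' @return 4 x 4 numeric matrix of R-squared values.
#' @export
index_correlation_matrix <- function(table) {
  cols <- c("rao_q", "cv", "shannon_rs", "simpson_d")
  if (!all(cols %in% names(table)))
    stop("table must have columns ", paste(cols, collapse = ", "))
  m <- as.matrix(table[, cols])
  m <- m[stats::complete.cases(m), , drop = FALSE]
  if (nrow(m) < 3L) stop("need at least 3 complete plots")
  if (any(apply(m, 2L, stats::var) == 0)) stop("constant index column")
  r2 <- stats::cor(m)^2
  diag(r2) <- 1
  r2
}
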
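test_that("rmse and mae match closed forms and inputs are validated", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(mae(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(0, 0), c(3, 4)), sqrt(25 / 2))
  expect_equal(mae(c(0, 0), c(3, 4)), 3.5)
  expect_equal(rmse(1, 4), 3)
  # constant offset: both equal |c|
  x <- runif(20); expect_equal(rmse(x, x + 2.5), 2.5)
  expect_equal(mae(x, x + 2.5), 2.5)
  expect_error(rmse(1:3, 1:4), "mismatch")
  expect_error(mae(numeric(0), numeric(0)), "empty")
})

test_that("rmse >= mae always, with equality only at a single residual magnitude", {
  set.seed(21)
  for (i in 1:200) {
    n <- sample(1:50, 1)
    x <- rnorm(n); y <- rnorm(n)
    expect_gte(rmse(x, y) + 1e-12, mae(x, y))
  }
  # equal magnitudes -> equality
  expect_equal(rmse(c(0, 0, 0), c(2, -2, 2)), mae(c(0, 0, 0), c(2, -2, 2)))
})

test_that("CHM validation recovers identity, offset and noise regimes", {
  set.seed(22)
  g <- raster_grid(matrix(runif(400, 0, 30), 20, 20), 10, origin = c(0, 200))
  plots <- plot_geometry(c("a", "b"), c(50, 150), c(50, 150))
  v <- suppressWarnings(validate_chm(g, g, plots))
  expect_equal(v$r_squared, 1)
  expect_equal(v$rmse, 0)
  expect_equal(v$mae, 0)
  expect_equal(v$n, 200)
  # constant +3 m offset: perfect correlation, errors equal the bias
  g3 <- raster_grid(g$values + 3, 10, origin = c(0, 200))
  v3 <- suppressWarnings(validate_chm(g3, g, plots))
  expect_equal(v3$r_squared, 1)
  expect_equal(v3$rmse, 3)
  expect_equal(v3$mae, 3)
  expect_equal(v3$bias, 3)
  # white noise independent of the reference: R2 near 0 at n = 10000
  big <- raster_grid(matrix(runif(10000, 0, 30), 100, 100), 10,
                     origin = c(0, 1000))
  noise <- raster_grid(matrix(runif(10000, 0, 30), 100, 100), 10,
                       origin = c(0, 1000))
  pall <- plot_geometry("all", 500, 500, 1000)
  vn <- validate_chm(noise, big, pall)
  expect_lt(vn$r_squared, 0.05)
  expect_error(validate_chm(aggregate_raster(g, 2), g, plots), "cell size")
})

test_that("simple regression reports slope, intercept, R2 and p per OLS", {
  x <- seq(0, 10, length.out = 30)
  f <- suppressWarnings(fit_linear(x, 2 * x + 1))
  expect_equal(f$r_squared, 1)
  expect_lt(f$p_value, 1e-12)
  expect_equal(unname(coef(f)), c(1, 2))
  expect_equal(f$rmse, 0, tolerance = 1e-10)
  expect_error(fit_linear(rep(1, 10), rnorm(10)), "zero variance")
  # R2 equals the squared Pearson correlation
  set.seed(23)
  y <- 2 * x + rnorm(30)
  expect_equal(fit_linear(x, y)$r_squared, cor(x, y)^2)
})

test_that("regression on an unrelated response gives small R2 across seeds", {
  r2 <- p <- numeric(20)
  for (s in 1:20) {
    set.seed(100 + s)
    x <- rnorm(130); y <- rnorm(130)
    f <- fit_linear(x, y)
    r2[s] <- f$r_squared; p[s] <- f$p_value
  }
  expect_lt(median(r2), 0.05)
  expect_gt(median(p), 0.05)
})

test_that("multiple regression nests the single model and flags collinearity", {
  set.seed(24)
  n <- 60
  hh <- runif(n); cc <- runif(n, 50, 100); dens <- rpois(n, 700)
  y <- 3 * hh + rnorm(n, sd = 0.3)
  single <- fit_linear(hh, y)
  multi <- fit_multiple(data.frame(hh = hh, canopy_cover = cc,
                                   density = dens), y)
  expect_gte(multi$r_squared, single$r_squared)
  # exact two-predictor relation
  y2 <- hh + 0.01 * cc
  f2 <- suppressWarnings(fit_multiple(data.frame(hh = hh, cc = cc), y2))
  expect_equal(f2$r_squared, 1)
  expect_error(fit_multiple(data.frame(a = hh, b = hh), y), "collinear")
})

test_that("OLS fit quality is invariant to predictor standardization", {
  set.seed(25)
  x <- runif(50, 0, 5); y <- 1.5 * x + rnorm(50)
  raw <- fit_linear(x, y)
  std <- fit_linear(scale(x)[, 1], y)
  expect_equal(std$r_squared, raw$r_squared)
  expect_equal(std$p_value, raw$p_value)
})

test_that("repeated k-fold CV is exact on noiseless data and seed-deterministic", {
  x <- seq(1, 130); y <- 0.5 * x + 2
  cv <- repeated_kfold_cv(x, y, k = 10, repeats = 3, seed = 5)
  expect_equal(nrow(cv$per_fold), 30)
  expect_gt(cv$mean_r2, 0.999)
  expect_lt(cv$mean_rmse, 1e-8)
  cv2 <- repeated_kfold_cv(x, y, k = 10, repeats = 3, seed = 5)
  expect_identical(cv$per_fold, cv2$per_fold)
  cv3 <- repeated_kfold_cv(x, y, k = 10, repeats = 3, seed = 6)
  expect_false(identical(cv$per_fold$r_squared, cv3$per_fold$r_squared))
  expect_error(repeated_kfold_cv(1:10, 1:10, k = 10, repeats = 3, seed = 1),
               "2k")
  expect_error(repeated_kfold_cv(x, y, k = 10, repeats = 3), "seed")
})

test_that("CV means are the arithmetic means of the per-fold metrics", {
  set.seed(26)
  x <- runif(60); y <- x + rnorm(60, sd = 0.5)
  cv <- repeated_kfold_cv(x, y, k = 5, repeats = 2, seed = 3)
  expect_equal(cv$mean_r2, mean(cv$per_fold$r_squared))
  expect_equal(cv$mean_rmse, mean(cv$per_fold$rmse))
  expect_equal(cv$mean_mae, mean(cv$per_fold$mae))
  expect_equal(nrow(cv$per_fold), 10)
})

test_that("held-out variance explained does not beat training R2 on average", {
  # the optimism property holds for the 1 - SSE/SST convention; the
  # fold-correlation convention has a positive small-sample bias instead
  diff <- numeric(20)
  for (s in 1:20) {
    set.seed(400 + s)
    x <- runif(130); y <- x + rnorm(130, sd = 1)
    train <- fit_linear(x, y)$r_squared
    cvr <- repeated_kfold_cv(x, y, k = 10, repeats = 2, seed = s)
    diff[s] <- train - cvr$pooled_r2_sst
    expect_lte(cvr$pooled_r2_sst, cvr$pooled_r2 + 1e-12)
  }
  expect_gt(mean(diff), 0)
})

test_that("the inter-index R2 matrix is symmetric with unit diagonal", {
  set.seed(27)
  tab <- data.frame(rao_q = runif(40), cv = runif(40),
                    shannon_rs = runif(40), simpson_d = runif(40))
  m <- index_correlation_matrix(tab)
  expect_equal(diag(m), c(rao_q = 1, cv = 1, shannon_rs = 1, simpson_d = 1))
  expect_equal(m, t(m))
  expect_true(all(m >= 0 & m <= 1))
  # a linear dependence gives R2 exactly 1
  tab$cv <- 2 * tab$rao_q
  expect_equal(index_correlation_matrix(tab)["rao_q", "cv"], 1)
  # independent columns at large n have small off-diagonals
  set.seed(28)
  big <- data.frame(rao_q = runif(2000), cv = runif(2000),
                    shannon_rs = runif(2000), simpson_d = runif(2000))
  mb <- index_correlation_matrix(big)
  expect_lt(max(mb[upper.tri(mb)]), 0.01)
  tab$simpson_d <- 1
  expect_error(index_correlation_matrix(tab), "constant")
})

test_that("validate_chm and fit_linear share the R2 estimator", {
  set.seed(29)
  g <- raster_grid(matrix(runif(100, 0, 30), 10, 10), 10, origin = c(0, 100))
  h <- raster_grid(pmax(g$values + rnorm(100, sd = 2), 0), 10,
                   origin = c(0, 100))
  plots <- plot_geometry("p", 50, 50)
  v <- validate_chm(h, g, plots)
  f <- fit_linear(as.vector(g$values), as.vector(h$values))
  expect_equal(v$r_squared, f$r_squared)
})
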
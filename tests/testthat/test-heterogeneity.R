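test_that("Rao's Q matches hand-computed pair sums", {
  # 6 ordered pairs at distance 4 among N = 4 pixels: 24 / 16
  expect_equal(rao_q(c(0, 0, 0, 4)), 1.5)
  # half-squared distance gives the population variance
  expect_equal(rao_q(c(0, 0, 0, 4), "half_squared"), 3.0)
  expect_equal(rao_q(rep(7.7, 25)), 0)
  expect_equal(rao_q(rep(7.7, 25), "half_squared"), 0)
  expect_equal(rao_q(5), 0)
  expect_error(rao_q(numeric(0)), "empty")
})

test_that("fast Rao's Q equals the O(N^2) oracle on random windows", {
  set.seed(11)
  for (i in 1:40) {
    x <- random_heights(sample(2:100, 1))
    for (d in c("euclidean", "half_squared")) {
      got <- rao_q(x, d); want <- rao_oracle(x, d)
      expect_lt(abs(got - want) / max(want, 1e-300), 1e-10)
    }
  }
})

test_that("half-squared Rao's Q is the population variance", {
  set.seed(12)
  for (i in 1:25) {
    x <- random_heights(sample(2:500, 1))
    vpop <- mean((x - mean(x))^2)
    expect_equal(rao_q(x, "half_squared"), vpop, tolerance = 1e-12)
  }
})

test_that("indices shift and scale the way the definitions dictate", {
  set.seed(13)
  x <- random_heights(60)
  s <- 2.75; const <- 11.5
  expect_equal(rao_q(x + const), rao_q(x))
  expect_equal(rao_q(x + const, "half_squared"), rao_q(x, "half_squared"))
  expect_equal(rao_q(x * s), s * rao_q(x))
  expect_equal(rao_q(x * s, "half_squared"), s^2 * rao_q(x, "half_squared"))
  expect_equal(sd(x + const), sd(x))
  # CV is not shift-invariant but is scale-invariant
  expect_false(isTRUE(all.equal(coefficient_of_variation(x + const),
                                coefficient_of_variation(x))))
  expect_equal(coefficient_of_variation(x * s), coefficient_of_variation(x))
  # class-abundance indices: shifting by whole classes leaves them unchanged
  expect_equal(shannon_rs(x + const), shannon_rs(x))
  expect_equal(simpson_d(x + const), simpson_d(x))
})

test_that("CV uses the sample SD over the mean and rejects a zero mean", {
  expect_equal(coefficient_of_variation(c(1, 3)), sqrt(2) / 2)
  expect_equal(coefficient_of_variation(c(5, 5, 5)), 0)
  expect_error(coefficient_of_variation(c(0, 0, 0)), "mean")
  expect_error(coefficient_of_variation(5), "two pixels")
  # population variant
  expect_equal(coefficient_of_variation(c(1, 3), sd_type = "population"),
               1 / 2)
})

test_that("window Shannon and Simpson follow class-abundance closed forms", {
  expect_equal(shannon_rs(c(10, 10, 20, 20)), log(2))
  expect_equal(shannon_rs(rep(4.2, 9)), 0)
  k <- 7
  expect_equal(shannon_rs(seq_len(k) * 1.0), log(k))
  expect_equal(simpson_d(c(10, 10, 20, 20)), 0.5)
  expect_equal(simpson_d(rep(4.2, 9)), 1)
  expect_equal(simpson_d(c(3, 7, 11, 19)), 0.25)
  # q equal-abundance classes: Hrs = log q, D = 1/q
  x <- rep(seq(2, 20, by = 2), each = 5)
  expect_equal(shannon_rs(x), log(10))
  expect_equal(simpson_d(x), 1 / 10)
})

test_that("height-class rounding is explicit and pinned at 0 and 1 digits", {
  x <- c(10.04, 10.06, 10.04, 10.06)
  expect_equal(shannon_rs(x, round_digits = 1), log(2))   # 10.0 vs 10.1
  expect_equal(shannon_rs(x, round_digits = 0), 0)        # one class: 10
  expect_equal(simpson_d(x, round_digits = 1), 0.5)
  expect_equal(simpson_d(x, round_digits = 0), 1)
})

test_that("abundance-only indices ignore which height value holds which class", {
  # swap the class values (10 <-> 30) keeping the abundance profile
  a <- c(rep(10, 6), rep(30, 2))
  b <- c(rep(30, 6), rep(10, 2))
  expect_equal(shannon_rs(a), shannon_rs(b))
  expect_equal(simpson_d(a), simpson_d(b))
  # Rao's Q and CV do react to the values
  aa <- c(rep(10, 6), rep(30, 2)); bb <- c(rep(10, 6), rep(50, 2))
  expect_false(isTRUE(all.equal(rao_q(aa), rao_q(bb))))
})

test_that("plot_heterogeneity composes the indices and reports rejects", {
  g <- raster_grid(matrix(5, 10, 10), 10, origin = c(0, 100))
  plots <- plot_geometry(c("const", "gone"), c(50, 9999), c(50, 9999))
  tab <- plot_heterogeneity(g, plots, chm_source = "test")
  expect_equal(nrow(tab), 1)
  expect_equal(tab$rao_q, 0)
  expect_equal(tab$cv, 0)
  expect_equal(tab$shannon_rs, 0)
  expect_equal(tab$simpson_d, 1)
  expect_equal(tab$n_pixels, 100)
  rej <- attr(tab, "rejects")
  expect_equal(rej$plot_id, "gone")
  # identical plots over identical pixels give identical rows
  p2 <- plot_geometry(c("a", "b"), c(50, 50), c(50, 50))
  t2 <- plot_heterogeneity(g, p2)
  expect_equal(t2[1, -1], t2[2, -1], ignore_attr = TRUE)
  # an all-nodata plot is rejected, not dropped silently
  v <- matrix(5, 10, 10); v[, 1:5] <- NA
  g3 <- raster_grid(v, 10, origin = c(0, 100))
  p3 <- plot_geometry(c("ok", "nodata"), c(75, 25), c(50, 50), side = 50)
  t3 <- suppressWarnings(plot_heterogeneity(g3, p3))
  expect_equal(attr(t3, "rejects")$plot_id, "nodata")
})

test_that("the moving-window map equals per-pixel Rao's Q with nodata borders", {
  # worked 3 x 3 example: single interior value (1/81) * sum of distances
  g <- raster_grid(matrix(c(0, 0, 0, 0, 0, 0, 0, 0, 9), 3, 3,
                          byrow = TRUE), 1)
  m <- rao_moving_window_map(g, 3)
  expect_equal(m$values[2, 2], 2 * 8 * 9 / 81)
  expect_equal(sum(!is.na(m$values)), 1)
  # constant grid: interior all 0, border nodata
  k <- rao_moving_window_map(raster_grid(matrix(4, 6, 8), 1), 3)
  expect_true(all(k$values[2:5, 2:7] == 0))
  expect_true(all(is.na(k$values[c(1, 6), ])))
  expect_true(all(is.na(k$values[, c(1, 8)])))
  # defining identity on random interior pixels
  set.seed(14)
  g2 <- raster_grid(matrix(runif(20 * 15, 0, 30), 20, 15), 1)
  m2 <- rao_moving_window_map(g2, 5)
  for (i in 1:15) {
    r <- sample(3:18, 1); cc <- sample(3:13, 1)
    expect_identical(m2$values[r, cc],
                     rao_q(as.vector(g2$values[(r - 2):(r + 2),
                                               (cc - 2):(cc + 2)])))
  }
  expect_error(rao_moving_window_map(g2, 4), "odd")
  expect_error(rao_moving_window_map(g, 5), "larger than grid")
})

test_that("nodata inside a moving window is excluded; sparse windows go nodata", {
  v <- matrix(10, 5, 5); v[2, 2] <- 20; v[1:3, 4:5] <- NA
  g <- raster_grid(v, 1)
  m <- rao_moving_window_map(g, 3)
  # window at (2,2) is complete: mixed values
  expect_equal(m$values[2, 2], rao_q(as.vector(v[1:3, 1:3])))
  # window at (2,4) keeps its 3 valid pixels
  expect_equal(m$values[2, 4], rao_q(v[1:3, 3:5][!is.na(v[1:3, 3:5])]))
  # fewer than 2 valid pixels in the window -> nodata output
  v1 <- matrix(NA_real_, 3, 3); v1[2, 2] <- 10
  m1 <- rao_moving_window_map(raster_grid(v1, 1), 3)
  expect_true(is.na(m1$values[2, 2]))
})
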
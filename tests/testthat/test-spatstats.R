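test_that("depth histograms count cells into 25 µm bins", {
  cells <- data.frame(depth = c(10, 30, 30), is_vol = c(TRUE, FALSE, TRUE))
  h <- depth_histogram(cells, 50)
  expect_equal(h$n_total, c(1L, 2L))
  expect_equal(h$n_vol, c(1L, 1L))
  expect_equal(h$bin_lo, c(0, 25))
  all_vol <- data.frame(depth = c(5, 40, 42), is_vol = TRUE)
  h2 <- depth_histogram(all_vol, 50)
  expect_equal(h2$n_vol, h2$n_total)
  out <- data.frame(depth = c(10, 60), is_vol = FALSE, id = c(7L, 9L))
  expect_error(depth_histogram(out, 50), "id 9")
})

test_that("layer statistics convert counts to densities per 1e6 µm³", {
  cells <- data.frame(depth = runif(27, 0, 100), is_vol = FALSE)
  ls <- layer_stats(cells, c(0, 100), section_area = 100 * 100)
  expect_equal(ls$density, 27)   # 27 cells in 1e6 µm³
  empty <- layer_stats(data.frame(depth = numeric(0), is_vol = logical(0)),
                       c(0, 100), section_area = 1e4)
  expect_equal(empty$density, 0)
  expect_true(is.na(empty$vol_pct))
  expect_error(layer_stats(cells, c(0, 50, 50), 1), "increasing")
})

test_that("per-layer vOL percentages aggregate exactly to the global percentage", {
  set.seed(4)
  cells <- data.frame(depth = runif(200, 0, 500),
                      is_vol = runif(200) < 0.2)
  ls <- layer_stats(cells, seq(0, 500, by = 100), section_area = 1e4)
  ok <- !is.na(ls$vol_pct)
  agg <- sum(ls$vol_pct[ok] * ls$n[ok]) / sum(ls$n[ok])
  expect_equal(agg, 100 * mean(cells$is_vol), tolerance = 1e-12)
})

test_that("density-occupancy correlation recovers exact lines and rejects constants", {
  x <- c(1, 2, 3, 4, 5)
  fit <- density_occupancy_correlation(x, 2 * x)
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 0, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1)
  expect_error(density_occupancy_correlation(rep(1, 5), x), "constant")
  expect_error(density_occupancy_correlation(x[1:2], x[1:2]), "3")
})

test_that("uncorrelated pairs give small R² and coupled renders give large R²", {
  set.seed(11)
  r2 <- replicate(20, {
    density_occupancy_correlation(rnorm(100), rnorm(100))$r_squared
  })
  expect_lt(median(r2), 0.1)
  # density-coupled occupancy
  d <- runif(10, 10, 50)
  occ <- 0.01 * d + rnorm(10, sd = 0.01)
  expect_gt(density_occupancy_correlation(d, occ)$r_squared, 0.8)
})

test_that("the flip null moves only vasculature channels and reverses on attached scenes", {
  p <- phantom_params(seed = 51L, volume_shape = c(70L, 150L, 150L),
                      n_somata = 25L, attached_fraction = 0.5,
                      vessel_length_density = 1e-3,
                      diameter_weights = c(capillary = 1, intermediate = 0,
                                           large = 0),
                      channels = c("vessel", "soma", "basement"))
  ph <- simulate_phantom(p)
  fn <- flip_null(ph$volume)
  expect_lt(fn$flipped, fn$observed)
  # flip axis leaves the soma channel identical
  fv <- flip_channels(ph$volume, c("vessel", "basement"))
  expect_identical(fv$data[, , , 2], ph$volume$data[, , , 2])
})

test_that("group comparison follows the normality-gated decision rule", {
  set.seed(21)
  a <- rnorm(20); b <- rnorm(20) + 3
  res <- compare_groups(list(a = a, b = b))
  expect_match(res$test, "t-test")
  expect_lt(res$p_value, 0.05)

  same <- compare_groups(list(a = a, b = a + rnorm(20, sd = 1e-3)))
  expect_gt(same$p_value, 0.5)

  skewed <- compare_groups(list(a = rexp(30), b = rexp(30)))
  expect_equal(res$branch, "normal")
  expect_equal(skewed$branch, "nonparametric")

  three <- compare_groups(list(a = runif(10), b = runif(10), c = runif(10)))
  expect_equal(three$test, "Kruskal-Wallis")

  expect_warning(tiny <- compare_groups(list(a = 1:2, b = 3:4)), "< 3")
  expect_equal(tiny$branch, "nonparametric")
  expect_error(compare_groups(list(a = 1:5)), "two groups")
})

test_that("paired comparisons use the paired branches", {
  set.seed(31)
  x <- rnorm(15)
  res <- compare_groups(list(x, x + 1 + rnorm(15, sd = 0.2)), paired = TRUE)
  expect_match(res$test, "paired|signed")
  expect_lt(res$p_value, 0.01)
})
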
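test_that("thresholding removes sub-size speckles and is idempotent", {
  arr <- array(0, c(10, 20, 20, 1))
  arr[4:6, 5:12, 5:12, 1] <- 1          # a real object
  arr[2, 2, 2, 1] <- 1                  # 1-voxel speckle
  arr[8, 16, 16, 1] <- 1; arr[8, 16, 17, 1] <- 1  # 2-voxel speckle
  v <- volume(arr, c(0.5, 0.5, 0.5), "vessel")
  m <- threshold_mask(v, "vessel", method = "fixed", threshold = 0.5,
                      min_component_size = 3L)
  expect_false(m[2, 2, 2])
  expect_false(m[8, 16, 16])
  expect_true(all(m[4:6, 5:12, 5:12]))
  m2 <- despeckle(m, 3L)
  expect_identical(as.logical(m2), as.logical(m))
})

test_that("an all-zero channel yields an empty mask with a warning, not an error", {
  v <- volume(array(0, c(4, 4, 4, 1)), c(1, 1, 1), "vessel")
  expect_warning(m <- threshold_mask(v, "vessel"), "all zero")
  expect_false(any(m))
})

test_that("noise-free tube masks match the analytic tube within a boundary band", {
  p <- tube_phantom_params(radius = 3)
  net <- generate_vessel_network(p)
  v <- render_volume(net, NULL, p)
  m <- threshold_mask(v, "vessel", method = "fixed", threshold = 0.5)
  d <- dim(m)
  idx <- arrayInd(seq_along(m), d)
  pts <- sweep(idx - 0.5, 2, v$voxel_size, "*")
  sd <- perivasc:::vessel_surface_distance(pts, net)
  band <- max(v$voxel_size)
  expect_true(all(m[sd < -band]))       # deep interior always in the mask
  expect_true(all(!m[sd > band]))       # clear exterior never in the mask
})

test_that("myelin occupancy hits the trivial bounds and counts real pixels", {
  arr <- array(1, c(4, 60, 60, 1))
  v <- volume(arr, c(0.5, 0.5, 0.5), "myelin")
  roi <- list(plane = 2L, a2 = c(5, 25), a3 = c(5, 25))
  expect_equal(myelin_occupancy(v, "myelin", roi, method = "fixed",
                                threshold = 0.5), 1.0)
  v0 <- volume(array(0, c(4, 60, 60, 1)), c(0.5, 0.5, 0.5), "myelin")
  expect_equal(myelin_occupancy(v0, "myelin", roi), 0.0)
  expect_error(myelin_occupancy(v, "myelin",
                                list(plane = 99L, a2 = c(0, 5), a3 = c(0, 5))),
               "outside")

  # rendered filament fraction vs direct pixel counting (same threshold)
  p <- phantom_params(volume_shape = c(20L, 120L, 120L),
                      voxel_size = c(0.5, 0.5, 0.5), seed = 13L,
                      vessel_length_density = 1e-4, n_somata = 1L,
                      diameter_weights = c(capillary = 1, intermediate = 0,
                                           large = 0),
                      channels = "myelin", myelin_density = 0.2,
                      depth_gradient = 1, noise = c(0, 0),
                      psf_sigma = c(0, 0, 0))
  ph <- simulate_phantom(p)
  sl <- get_channel(ph$volume, "myelin")[10, 11:50, 11:50]
  direct <- mean(sl >= 0.5)
  meas <- myelin_occupancy(ph$volume, "myelin",
                           list(plane = 10L, a2 = c(5, 25), a3 = c(5, 25)),
                           method = "fixed", threshold = 0.5)
  expect_lt(abs(meas - direct), 0.02)
})

test_that("vascular density matches the analytic projection of a cylinder", {
  p <- tube_phantom_params(radius = 3, shape = c(40L, 80L, 80L))
  net <- generate_vessel_network(p)
  v <- render_volume(net, NULL, p)
  ext <- vol_extent(v)
  L <- ext[3] - 4  # tube spans a3 from 2 to ext-2
  expected <- 2 * 3 * L / (ext[2] * ext[3] * ext[1])
  got <- vascular_density(v, "vessel", method = "fixed", threshold = 0.5)
  expect_equal(got, expected, tolerance = 0.15)
  v0 <- volume(array(0, c(4, 10, 10, 1)), c(1, 1, 1), "vessel")
  expect_equal(vascular_density(v0, "vessel"), 0)
})

test_that("straight cylinders extract as a single acyclic edge with the right radius", {
  for (r in c(2, 3, 4)) {
    p <- tube_phantom_params(radius = r, seed = 3L)
    net <- generate_vessel_network(p)
    v <- render_volume(net, NULL, p)
    m <- threshold_mask(v, "vessel", method = "fixed", threshold = 0.5)
    x <- extract_network(m, v$voxel_size)
    expect_length(x$edges, 1L)
    expect_equal(nrow(x$branch_nodes), 0L)
    med <- median(x$edges[[1]]$radius)
    expect_lt(abs(med - r), max(v$voxel_size))
    # acyclic: an open polyline has distinct endpoints
    e <- x$edges[[1]]
    expect_gt(sqrt(sum((e$points[1, ] - e$points[nrow(e$points), ])^2)), 1)
  }
})

test_that("a Y-junction yields exactly one branch node near the true junction", {
  p <- y_phantom_params()
  net <- generate_vessel_network(p)
  expect_equal(nrow(net$branch_nodes), 1L)   # ground truth
  v <- render_volume(net, NULL, p)
  m <- threshold_mask(v, "vessel", method = "fixed", threshold = 0.5)
  x <- extract_network(m, v$voxel_size)
  expect_equal(nrow(x$branch_nodes), 1L)
  expect_lt(sqrt(sum((x$branch_nodes[1, ] - c(10, 20, 20))^2)), 3)
})

test_that("empty masks give empty networks with a warning", {
  m <- array(FALSE, c(5, 5, 5))
  expect_warning(x <- extract_network(m, c(1, 1, 1)), "empty")
  expect_length(x$edges, 0L)
})

test_that("well-separated somata are each detected with sub-voxel centroids", {
  p <- phantom_params(seed = 41L, n_somata = 10L, attached_fraction = 0,
                      volume_shape = c(80L, 160L, 160L),
                      diameter_weights = c(capillary = 1, intermediate = 0,
                                           large = 0),
                      channels = c("vessel", "soma"),
                      noise = c(300, 0.005))
  ph <- simulate_phantom(p)
  ss <- segment_somata(ph$volume, "soma")
  expect_length(ss, 10L)
  tr <- as.matrix(ph$truth$somata[, c("c1", "c2", "c3")])
  for (s in ss) {
    derr <- min(sqrt(colSums((t(tr) - s$centroid)^2)))
    expect_lt(derr, max(ph$volume$voxel_size))
    expect_true(mesh_is_watertight(s$mesh))
  }
  expect_length(segment_somata(volume(array(0, c(4, 4, 4, 1)), c(1, 1, 1),
                                      "soma"), "soma"), 0L)
})

test_that("a rendered sphere's mesh area approximates the closed form", {
  # analytic ball field, smoothed, meshed at the half level
  g <- seq(0.125, 14, by = 0.25)
  f <- array(0, c(length(g), length(g), length(g)))
  for (i in seq_along(g))
    f[i, , ] <- (outer((g - 7)^2, (g - 7)^2, "+") + (g[i] - 7)^2 <= 25) * 1
  perivasc:::.gauss_blur3_cpp(f, dim(f), rep(0.7, 3))
  mesh <- mesh_from_field(f, rep(0.25, 3), 0.5)
  expect_true(mesh_is_watertight(mesh))
  expect_equal(mesh_area(mesh), 4 * pi * 25, tolerance = 0.1)
})
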
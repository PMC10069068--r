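test_that("parameter validation enforces the geometric invariants", {
  expect_error(phantom_params(attached_fraction = 1.2), "attached_fraction")
  expect_error(phantom_params(voxel_size = c(0.5, -1, 0.5)), "voxel_size")
  expect_error(phantom_params(marker_offsets = c(pericyte = 0.1,
                                                 endothelial = 0.3,
                                                 basement = 0.08)),
               "ordered")
  expect_error(phantom_params(attach_gap_max = 0.2), "0.1")
})

test_that("a single straight tube request yields one unbranched edge with the requested radius", {
  p <- tube_phantom_params(radius = 3)
  net <- generate_vessel_network(p)
  expect_length(net$edges, 1L)
  expect_equal(nrow(net$branch_nodes), 0L)
  expect_true(all(net$edges[[1]]$radius == 3))
})

test_that("capillary-only mixtures generate only sub-8-µm diameters", {
  p <- phantom_params(diameter_weights = c(capillary = 1, intermediate = 0,
                                           large = 0),
                      seed = 5L)
  net <- generate_vessel_network(p)
  expect_gt(length(net$edges), 0L)
  diam <- 2 * unlist(lapply(net$edges, `[[`, "radius"))
  expect_true(all(diam < 8))
})

test_that("network generation is deterministic for a fixed seed", {
  p <- phantom_params(seed = 17L)
  n1 <- generate_vessel_network(p)
  n2 <- generate_vessel_network(p)
  expect_identical(n1$edges, n2$edges)
  expect_identical(n1$branch_nodes, n2$branch_nodes)
})

test_that("a volume too small for the requested calibers fails loudly", {
  p <- phantom_params(volume_shape = c(20L, 20L, 20L),
                      voxel_size = c(0.5, 0.5, 0.5),
                      diameter_weights = c(capillary = 0, intermediate = 0,
                                           large = 1))
  expect_error(generate_vessel_network(p), "too small")
})

test_that("soma placement honors the attached fraction and the gap margins", {
  p <- phantom_params(seed = 23L, n_somata = 40L, attached_fraction = 0.17,
                      channels = "vessel")
  net <- generate_vessel_network(p)
  som <- place_somata(net, p)
  df <- som$somata
  expect_equal(sum(df$attached), round(0.17 * 40))
  expect_true(all(df$true_gap[df$attached] <= 0.1))
  expect_true(all(df$true_gap[!df$attached] > 2))
  # no soma-soma overlap
  ctr <- as.matrix(df[, c("c1", "c2", "c3")])
  D <- as.matrix(dist(ctr))
  diag(D) <- Inf
  rsum <- outer(df$radius, df$radius, "+")
  expect_true(all(D > rsum))
})

test_that("attached fraction 0 and 1 hit the boundary contracts", {
  p0 <- phantom_params(seed = 29L, n_somata = 10L, attached_fraction = 0,
                       channels = "vessel")
  net <- generate_vessel_network(p0)
  s0 <- place_somata(net, p0)
  expect_true(all(s0$somata$true_gap > 2))

  p1 <- phantom_params(seed = 29L, n_somata = 8L, attached_fraction = 1,
                       channels = "vessel")
  s1 <- place_somata(net, p1)
  expect_true(all(s1$somata$true_gap <= 0.1))
})

test_that("recorded wall gaps match a brute-force surface-distance oracle", {
  p <- phantom_params(seed = 31L, n_somata = 8L, attached_fraction = 0.5,
                      channels = "vessel")
  net <- generate_vessel_network(p)
  som <- place_somata(net, p)
  df <- som$somata
  for (i in seq_len(nrow(df))) {
    g <- brute_force_gap(unlist(df[i, c("c1", "c2", "c3")]), df$radius[i],
                         net, gap = if (df$attached[i]) df$true_gap[i])
    expect_equal(g, df$true_gap[i], tolerance = 1e-3,
                 label = paste("soma", i))
  }
})

test_that("rendering is deterministic and non-negative, and empty scenes stay empty", {
  p <- tube_phantom_params(radius = 2.5, n_somata = 2L,
                           channels = c("vessel", "soma"),
                           noise = c(150, 0.01))
  net <- generate_vessel_network(p)
  som <- place_somata(net, p)
  v1 <- render_volume(net, som, p)
  v2 <- render_volume(net, som, p)
  expect_identical(v1$data, v2$data)
  expect_true(all(v1$data >= 0))

  empty_net <- vessel_network(list(), extent = p$volume_shape * p$voxel_size)
  p0 <- tube_phantom_params(radius = 2.5, channels = "soma", noise = c(0, 0))
  v0 <- render_volume(empty_net, NULL, p0)
  expect_true(all(v0$data == 0))
})

test_that("noise- and PSF-free tubes render as analytic point-in-tube sets", {
  p <- tube_phantom_params(radius = 3)
  net <- generate_vessel_network(p)
  v <- render_volume(net, NULL, p)
  ch <- get_channel(v, "vessel")
  d <- dim(ch)
  idx <- arrayInd(seq_along(ch), d)
  pts <- sweep(idx - 0.5, 2, v$voxel_size, "*")
  sd <- perivasc:::vessel_surface_distance(pts, net)
  # strictly inside the tube: positive; clearly outside: zero
  expect_true(all(ch[sd < -1] > 0.9))
  expect_true(all(ch[sd > 1] == 0))
})

test_that("demyelination at survival 1 reproduces the baseline exactly", {
  p <- tube_phantom_params(radius = 2.5, n_somata = 6L,
                           shape = c(40L, 100L, 100L),
                           attached_fraction = 0.5,
                           channels = c("vessel", "soma"),
                           noise = c(150, 0.01))
  base <- simulate_phantom(p)
  s1 <- demyelination_scenario(p, 1)
  expect_identical(base$volume$data, s1$volume$data)
  expect_identical(base$truth$somata, s1$truth$somata)
})

test_that("demyelination scales both pools and preserves the attached proportion", {
  p <- phantom_params(seed = 37L, n_somata = 27L, attached_fraction = 0.2,
                      channels = c("vessel", "soma"))
  s3 <- demyelination_scenario(p, 1 / 3)
  expect_equal(nrow(s3$truth$somata), 9L)
  n_att_base <- round(0.2 * 27)
  expect_equal(sum(s3$truth$somata$attached), round(n_att_base / 3))
  expect_error(demyelination_scenario(p, 1.5), "survival_fraction")
})
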
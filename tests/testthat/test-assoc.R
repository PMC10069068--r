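# synthetic profile helper: two Gaussian peaks at known positions
make_profile <- function(pos, soma_pos, marker_pos, sd = 0.15,
                         soma_amp = 1, marker_amp = 1) {
  ch <- cbind(soma = soma_amp * exp(-(pos - soma_pos)^2 / (2 * sd^2)),
              basement = marker_amp * exp(-(pos - marker_pos)^2 / (2 * sd^2)))
  structure(list(position = pos, channels = ch, wall_position = NULL),
            class = "pv_profile")
}

test_that("contact lines run radially through the nearest vessel", {
  p <- tube_phantom_params(radius = 3, n_somata = 1L, attached_fraction = 1,
                           channels = c("vessel", "soma", "basement"))
  net <- generate_vessel_network(p)
  som <- place_somata(net, p)
  v <- render_volume(net, som, p)
  s <- list(centroid = unlist(som$somata[1, c("c1", "c2", "c3")]),
            radius_equiv = som$somata$radius[1])
  prof <- contact_line(v, s, net)
  expect_s3_class(prof, "pv_profile")
  expect_gte(length(prof$position), 16L)
  expect_true(all(diff(prof$position) > 0))
  # perpendicular to the tube axis (axis 3) within 5 degrees
  expect_lt(abs(prof$direction[3]), sin(5 * pi / 180))
})

test_that("somata without a vessel in the search radius yield no profile", {
  arr <- array(0, c(30, 30, 30, 2))
  v <- volume(arr, c(1, 1, 1), c("vessel", "soma"))
  net <- tube_network(list(list(start = c(1, 1, 1), end = c(1, 1, 29),
                                radius = 1)))
  far <- list(centroid = c(28, 28, 15), radius_equiv = 3)
  expect_null(contact_line(v, far, net, search_radius = 20))
  empty <- vessel_network(list())
  expect_null(contact_line(v, far, empty))
})

test_that("equidistant vessels resolve to the lowest edge id", {
  net <- tube_network(list(list(start = c(5, 2, 0), end = c(5, 2, 20), radius = 1),
                           list(start = c(5, 8, 0), end = c(5, 8, 20), radius = 1)))
  nv <- perivasc:::nearest_vessel(matrix(c(5, 5, 10), 1, 3), net)
  expect_equal(nv$edge, 1L)
})

test_that("peak distances recover constructed offsets to sub-sample precision", {
  pos <- seq(0, 10, by = 0.1)
  expect_equal(peak_distance(make_profile(pos, 5, 5), "soma", "basement"), 0,
               tolerance = 1e-6)
  p30 <- make_profile(pos, 5.00, 5.30)
  expect_equal(peak_distance(p30, "soma", "basement"), 0.30,
               tolerance = 0.02)
  # offset not an exact multiple of the sample step
  p17 <- make_profile(pos, 4.98, 5.15)
  expect_equal(peak_distance(p17, "soma", "basement"), 0.17,
               tolerance = 0.02)
  flat <- make_profile(pos, 5, 6)
  flat$channels[, "soma"] <- 1
  expect_error(peak_distance(flat, "soma", "basement"), "soma")
  expect_error(peak_distance(p30, "soma", "missing"), "missing")
})

test_that("the association rule is inclusive at 1 µm", {
  expect_true(classify_vol(1.0))
  expect_false(classify_vol(1.01))
  expect_true(classify_vol(0.08))
  expect_false(classify_vol(NA_real_))
  expect_error(classify_vol(-0.5), ">= 0")
})

test_that("vessel diameters come from the local centerline radius", {
  net <- tube_network(list(list(start = c(10, 10, 0), end = c(10, 10, 40),
                                radius = 3.45)))
  s <- list(centroid = c(10, 16, 20), radius_equiv = 3)
  expect_equal(vessel_diameter_at(s, net), 6.9, tolerance = 1e-6)
  far <- list(centroid = c(10, 40, 20), radius_equiv = 3)
  expect_true(is.na(vessel_diameter_at(far, net, search_radius = 20)))
})

test_that("caliber categories follow the stated boundaries", {
  expect_equal(as.character(categorize_vessel(6.9)), "capillary")
  expect_equal(as.character(categorize_vessel(8.0)), "intermediate")
  expect_equal(as.character(categorize_vessel(15.0)), "intermediate")
  expect_equal(as.character(categorize_vessel(15.01)), "large")
  expect_equal(as.character(categorize_vessel(20)), "large")
  expect_error(categorize_vessel(-1), "positive")
  expect_true(is.na(categorize_vessel(NA)))
})

test_that("bifurcation assignment uses the soma radius plus tolerance", {
  net <- tube_network(list(list(start = c(10, 20, 5), end = c(10, 20, 20), radius = 2),
                           list(start = c(10, 20, 20), end = c(10, 30, 30), radius = 2),
                           list(start = c(10, 20, 20), end = c(10, 10, 30), radius = 2)))
  on_j <- list(centroid = c(10, 20, 20), radius_equiv = 3)
  expect_true(at_bifurcation(on_j, net))
  away <- list(centroid = c(10, 20, 50), radius_equiv = 3)
  expect_false(at_bifurcation(away, net))
  no_branch <- tube_network(list(list(start = c(0, 0, 0), end = c(0, 0, 9),
                                      radius = 1)))
  expect_false(at_bifurcation(on_j, no_branch))
})

test_that("contact area is zero for disjoint surfaces and bounded by the soma surface", {
  p <- tube_phantom_params(radius = 2.5, shape = c(60L, 60L, 60L),
                           voxel = c(0.3, 0.3, 0.3), n_somata = 1L,
                           attached_fraction = 1,
                           channels = c("vessel", "soma"), seed = 5L)
  net <- generate_vessel_network(p)
  som <- place_somata(net, p)
  v <- render_volume(net, som, p)
  s <- segment_somata(v, "soma")[[1]]
  far_net <- tube_network(list(list(start = c(1, 1, 1), end = c(1, 1, 17),
                                    radius = 0.5)))
  ca0 <- contact_area(s, far_net)
  expect_equal(ca0$area, 0)
  expect_equal(ca0$fraction, 0)
  ca <- contact_area(s, net, contact_distance = 0.3)
  expect_lte(ca$area, s$surface_area)
  expect_lte(ca$fraction, 1)
  expect_gt(ca$area, 0)
})

test_that("the wrapped-cap contact area matches a numeric cap oracle", {
  # analytic scene: a sphere pressed onto a cylinder, wrapping over the
  # contact cap at a small wall gap
  R <- 3.5; rv <- 3; gap <- 0.02
  cap_angle <- 0.76
  axis <- c(0, 0, 1)
  base <- c(10, 10, 10)              # a point on the cylinder axis
  ctr <- base + c(0, rv + gap + R * cos(cap_angle), 0)
  vox <- 0.15
  g1 <- seq(vox / 2, 20, by = vox)
  field <- array(0, c(length(g1), length(g1), length(g1)))
  for (i in seq_along(g1)) {
    dax <- matrix(sqrt((g1[i] - base[1])^2 + (g1 - base[2])^2),
                  length(g1), length(g1))        # axis distance, (a2, a3)
    dc <- sqrt((g1[i] - ctr[1])^2 +
                 outer((g1 - ctr[2])^2, (g1 - ctr[3])^2, "+"))
    field[i, , ] <- pmin(R - dc, dax - (rv + gap))
  }
  mesh <- mesh_from_field(field, rep(vox, 3), 0)
  expect_true(mesh_is_watertight(mesh))
  soma <- list(mesh = mesh, surface_area = mesh_area(mesh))
  net <- tube_network(list(list(start = c(10, 10, 0), end = c(10, 10, 20),
                                radius = rv)))
  ca <- contact_area(soma, net, contact_distance = 0.1)

  # oracle: area of the cylinder patch (radius rv + gap) inside the sphere,
  # by dense numeric integration over the cylinder surface
  zs <- seq(-R, R, length.out = 800) + 10
  phis <- seq(0, 2 * pi, length.out = 721)[-721]
  inside <- 0
  for (z in zs) {
    pts <- cbind(10 + (rv + gap) * cos(phis), 10 + (rv + gap) * sin(phis),
                 z)
    inside <- inside + sum(rowSums(sweep(pts, 2, ctr)^2) <= R^2)
  }
  oracle <- inside / (length(zs) * length(phis)) *
    (2 * R) * (2 * pi * (rv + gap))
  expect_equal(ca$area, oracle, tolerance = 0.15)
  expect_equal(ca$fraction, ca$area / soma$surface_area)
})

test_that("marker intensity dips at the contact site when rendered with a dip", {
  p <- phantom_params(volume_shape = c(80L, 80L, 80L),
                      voxel_size = c(0.3, 0.3, 0.3),
                      fixed_tubes = list(list(start = c(12, 12, 2),
                                              end = c(12, 12, 22),
                                              radius = 2.5)),
                      n_somata = 1L, attached_fraction = 1, noise = c(0, 0),
                      psf_sigma = c(0, 0, 0),
                      channels = c("vessel", "soma", "aqp4"),
                      contact_dip = 0.4, seed = 6L)
  net <- generate_vessel_network(p)
  som <- place_somata(net, p)
  v <- render_volume(net, som, p)
  s <- segment_somata(v, "soma")[[1]]
  suppressWarnings(ic <- intensity_at_contact(v, "aqp4", s, net))
  expect_lt(ic$contact, mean(ic$control))
  expect_equal(ic$ratio, 0.6, tolerance = 0.1)

  # no-dip render: contact and control agree
  p0 <- p; p0$contact_dip <- 0
  v0 <- render_volume(net, som, p0)
  s0 <- segment_somata(v0, "soma")[[1]]
  suppressWarnings(ic0 <- intensity_at_contact(v0, "aqp4", s0, net))
  expect_equal(ic0$ratio, 1, tolerance = 0.05)
})

test_that("non-watertight meshes are rejected for contact-area measurement", {
  s <- list(mesh = list(vertices = rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                        faces = matrix(1:3, 1)),
            surface_area = 1)
  net <- tube_network(list(list(start = c(0, 0, 0), end = c(0, 0, 5),
                                radius = 1)))
  expect_error(contact_area(s, net), "watertight")
})
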
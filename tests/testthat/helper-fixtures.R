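# Shared fixtures, built once per test run and cached.
.fx <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fx)) assign(name, builder(), envir = .fx)
  get(name, envir = .fx)
}

# straight-tube phantom along axis 3, optional channels, clean imaging
tube_phantom_params <- function(radius, shape = c(40L, 60L, 60L),
                                voxel = c(0.5, 0.5, 0.5),
                                channels = "vessel", seed = 3L,
                                n_somata = 1L, attached_fraction = 1,
                                noise = c(0, 0), psf = c(0, 0, 0)) {
  ext <- shape * voxel
  phantom_params(volume_shape = shape, voxel_size = voxel,
                 fixed_tubes = list(list(start = c(ext[1] / 2, ext[2] / 2, 2),
                                         end = c(ext[1] / 2, ext[2] / 2,
                                                 ext[3] - 2),
                                         radius = radius)),
                 n_somata = n_somata, attached_fraction = attached_fraction,
                 noise = noise, psf_sigma = psf, channels = channels,
                 seed = seed)
}

# Y-junction phantom: three tubes sharing one endpoint
y_phantom_params <- function(channels = "vessel", seed = 3L) {
  phantom_params(
    volume_shape = c(40L, 80L, 80L), voxel_size = c(0.5, 0.5, 0.5),
    fixed_tubes = list(
      list(start = c(10, 20, 5), end = c(10, 20, 20), radius = 2.5),
      list(start = c(10, 20, 20), end = c(10, 32, 33), radius = 2.5),
      list(start = c(10, 20, 20), end = c(10, 8, 33), radius = 2.5)),
    n_somata = 1L, noise = c(0, 0), psf_sigma = c(0, 0, 0),
    channels = channels, seed = seed)
}

# a small analyzed census phantom shared between association tests
census_fixture <- function() {
  fixture("census", function() {
    p <- phantom_params(seed = 118L, n_somata = 50L, attached_fraction = 0.17,
                        channels = c("vessel", "soma", "basement"))
    ph <- simulate_phantom(p)
    an <- analyze_volume(ph$volume)
    list(params = p, phantom = ph, analysis = an)
  })
}

# Brute-force minimum distance from a soma surface to the analytic tube
# surfaces of a network (independent oracle). A detached soma is a plain
# sphere; an attached soma is the sphere clipped where it would penetrate
# within `gap` of its host vessel wall (the wall-following cap), so each
# surface point along a ray is either on the sphere or on the clip surface
# (found by bisection).
brute_force_gap <- function(center, R, network, gap = NULL, n_dir = 4000L) {
  set.seed(7)
  dirs <- matrix(rnorm(3 * n_dir), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  sdist <- function(pts) perivasc:::vessel_surface_distance(pts, network)
  if (is.null(gap)) {
    return(min(sdist(sweep(dirs * R, 2, center, "+"))))
  }
  at_t <- function(tv) sweep(dirs * tv, 2, center, "+")
  d_R <- sdist(at_t(R))
  out <- d_R
  cross <- d_R < gap  # ray exits through the clip surface, not the sphere
  if (any(cross)) {
    lo <- rep(0, sum(cross))
    hi <- rep(R, sum(cross))
    dc <- dirs[cross, , drop = FALSE]
    for (it in 1:40) {
      mid <- (lo + hi) / 2
      pm <- sweep(dc * mid, 2, center, "+")
      inside <- sdist(pm) < gap
      hi[inside] <- mid[inside]
      lo[!inside] <- mid[!inside]
    }
    out[cross] <- sdist(sweep(dc * hi, 2, center, "+"))
  }
  min(out)
}
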
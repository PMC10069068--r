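#' Parameters of the synthetic confocal phantom
#'
#' Defines the geometry, optics and noise of a seeded synthetic multi-channel
#' volume emulating a confocal stack of cortical tissue: a capillary-dominated
#' vessel network, vessel-wall marker shells at sub-micrometre offsets, a
#' controllable fraction of vessel-attached somata, a depth-increasing
#' soma/myelin density, Gaussian PSF blur and Poisson + Gaussian noise.
#'
#' @param volume_shape voxels per axis (axis 1 = optical z, axes 2-3 in plane).
#' @param voxel_size µm per voxel per axis; anisotropy allowed.
#' @param vessel_length_density µm of vessel centerline per µm³ of tissue.
#' @param diameter_weights mixture weights for the three caliber classes
#'   capillary (< 8 µm), intermediate (8-15 µm) and large (> 15 µm).
#' @param n_somata number of somata to place.
#' @param attached_fraction true fraction of vessel-attached somata in [0, 1].
#' @param soma_radius c(mean, sd) of the soma radius (µm).
#' @param marker_offsets named offsets (µm) of the pericyte, endothelial and
#'   basement-membrane shells from the soma-facing vessel wall; must be
#'   ordered pericyte >= endothelial >= basement >= 0.
#' @param depth_gradient multiplier of soma/myelin density at the deepest
#'   depth relative to the surface (1 = uniform).
#' @param psf_sigma Gaussian PSF sigma (µm) per axis; 0 disables blur.
#' @param noise c(poisson_scale, gaussian_sd): photons per intensity unit for
#'   shot noise (0 disables) and additive read-noise sd.
#' @param seed integer seed; fixes networks, placements, textures and noise.
#' @param channels which channels to render; any of "vessel" (filled
#'   vasculature label), "pericyte", "endothelial", "basement" (wall marker
#'   shells), "soma", "myelin", "aqp4".
#' @param depth_axis spatial axis of cortical depth (default 2, in plane).
#' @param branch_prob branching probability per µm of grown centerline.
#' @param step_len random-walk step length (µm).
#' @param bend_sd direction jitter per step (radians, controls tortuosity).
#' @param cap_angle half-angle (radians) of the spherical cap over which an
#'   attached soma is deformed to follow the vessel wall.
#' @param attach_gap_max attached somata sit at a wall gap drawn uniformly
#'   from [0, attach_gap_max] µm (must be <= 0.1).
#' @param detach_min_gap minimum wall gap (µm) enforced for detached somata.
#' @param myelin_density target myelin volume fraction at mid-depth.
#' @param contact_dip fractional intensity dip of the "aqp4" wall channel at
#'   soma contact sites (0 = none).
#' @param fixed_tubes optional list of `list(start, end, radius)` (µm)
#'   overriding the random network with explicit straight tubes.
#' @param placement "classified" places somata as attached/detached pools
#'   per `attached_fraction`; "random" places them uniformly without any
#'   vessel-distance constraint (the chance-association calibration scene).
#' @return validated parameter list of class `pv_params`.
#' @export
phantom_params <- function(volume_shape = c(100L, 250L, 250L),
                           voxel_size = c(0.5, 0.4, 0.4),
                           vessel_length_density = 1e-3,
                           diameter_weights = c(capillary = 0.92,
                                                intermediate = 0.06,
                                                large = 0.02),
                           n_somata = 30L,
                           attached_fraction = 0.17,
                           soma_radius = c(mean = 3.5, sd = 0.3),
                           marker_offsets = c(pericyte = 0.5,
                                              endothelial = 0.3,
                                              basement = 0.08),
                           depth_gradient = 2,
                           psf_sigma = c(0.35, 0.15, 0.15),
                           noise = c(poisson_scale = 200, gaussian_sd = 0.01),
                           seed = 1L,
                           channels = c("vessel", "soma", "basement"),
                           depth_axis = 2L,
                           branch_prob = 0.02,
                           step_len = 2,
                           bend_sd = 0.12,
                           cap_angle = 0.76,
                           attach_gap_max = 0.03,
                           detach_min_gap = 2.2,
                           myelin_density = 0.15,
                           contact_dip = 0.4,
                           fixed_tubes = NULL,
                           placement = c("classified", "random")) {
  p <- list(volume_shape = as.integer(volume_shape),
            voxel_size = as.numeric(voxel_size),
            vessel_length_density = vessel_length_density,
            diameter_weights = diameter_weights,
            n_somata = as.integer(n_somata),
            attached_fraction = attached_fraction,
            soma_radius = soma_radius,
            marker_offsets = marker_offsets,
            depth_gradient = depth_gradient,
            psf_sigma = as.numeric(psf_sigma),
            noise = noise,
            seed = as.integer(seed),
            channels = channels,
            depth_axis = as.integer(depth_axis),
            branch_prob = branch_prob, step_len = step_len, bend_sd = bend_sd,
            cap_angle = cap_angle, attach_gap_max = attach_gap_max,
            detach_min_gap = detach_min_gap,
            myelin_density = myelin_density, contact_dip = contact_dip,
            fixed_tubes = fixed_tubes,
            placement = match.arg(placement))
  validate_phantom_params(p)
  class(p) <- "pv_params"
  p
}

validate_phantom_params <- function(p) {
  if (length(p$volume_shape) != 3L || any(p$volume_shape < 2L))
    stop("volume_shape must be three voxel counts >= 2")
  if (length(p$voxel_size) != 3L || any(p$voxel_size <= 0))
    stop("voxel_size must be three positive values")
  if (p$attached_fraction < 0 || p$attached_fraction > 1)
    stop("attached_fraction must lie in [0, 1]")
  if (any(p$diameter_weights < 0) || sum(p$diameter_weights) <= 0)
    stop("diameter_weights must be non-negative with positive sum")
  if (p$soma_radius[[1]] <= 0) stop("soma radius mean must be > 0")
  mo <- p$marker_offsets
  need <- c("pericyte", "endothelial", "basement")
  if (!all(need %in% names(mo)))
    stop("marker_offsets must be named pericyte, endothelial, basement")
  if (!(mo[["pericyte"]] >= mo[["endothelial"]] &&
        mo[["endothelial"]] >= mo[["basement"]] && mo[["basement"]] >= 0))
    stop("marker_offsets must be ordered pericyte >= endothelial >= basement >= 0")
  if (p$attach_gap_max > 0.1)
    stop("attach_gap_max must be <= 0.1 µm (attached somata touch the wall)")
  if (p$detach_min_gap <= 2)
    stop("detach_min_gap must exceed 2 µm (clear margin around the 1 µm criterion)")
  if (p$depth_gradient <= 0) stop("depth_gradient must be > 0")
  invisible(p)
}

# class -> diameter (µm): capillary < 8, intermediate 8-15, large > 15
sample_diameter <- function(class) {
  switch(class,
         capillary = runif(1, 3, 7.5),
         intermediate = runif(1, 8, 15),
         large = runif(1, 15.5, 22))
}

# depth-density weight at normalized depth u in [0, 1]
depth_weight <- function(u, gradient) 1 + (gradient - 1) * u

#' Generate a synthetic vessel centerline network
#'
#' Grows random-walk centerline polylines with a per-length branching
#' probability until the requested centerline length density is reached.
#' Each vessel tree draws its caliber class from the configured mixture;
#' capillaries dominate as in cortical tissue where most vessels are
#' micro-vessels. Deterministic for a fixed seed.
#'
#' @param params a [phantom_params()].
#' @return a [vessel_network()] whose edges carry per-point radii; branch
#'   nodes are the recorded bifurcation points.
#' @export
generate_vessel_network <- function(params) {
  validate_phantom_params(params)
  extent <- params$volume_shape * params$voxel_size
  if (!is.null(params$fixed_tubes))
    return(tube_network(params$fixed_tubes, extent = extent))

  classes <- names(params$diameter_weights)
  wts <- params$diameter_weights / sum(params$diameter_weights)
  # a caliber class is feasible if its thinnest vessel fits inside the
  # volume with its placement margin; infeasible draws are skipped, but at
  # least one drawable class must fit
  min_diam <- c(capillary = 3, intermediate = 8, large = 15.5)
  feasible <- min(extent) > min_diam[classes] + 1
  if (!any(feasible & wts > 0))
    stop("volume too small to host any vessel at the requested calibers: ",
         "min extent ", round(min(extent), 1), " µm cannot contain the ",
         "thinnest requested vessel")

  with_seed(sub_seed(params$seed, 1L), {
    target <- params$vessel_length_density * prod(extent)
    edges <- list()
    branch_nodes <- NULL
    total <- 0
    guard <- 0L
    while (total < target && guard < 10000L) {
      guard <- guard + 1L
      cls <- sample(classes, 1L, prob = wts)
      diam <- sample_diameter(cls)
      r <- diam / 2
      margin <- r + 0.5
      if (any(extent - 2 * margin <= 0)) next
      start <- margin + runif(3) * (extent - 2 * margin)
      stack <- list(list(pos = start, dir = runit3(), r = r, spawn = NULL))
      while (length(stack) && total < target) {
        tr <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        pts <- matrix(tr$pos, 1L, 3L)
        dir <- tr$dir
        len <- 0
        maxlen <- runif(1, 60, 160)
        while (len < maxlen) {
          dir <- dir + rnorm(3, sd = params$bend_sd)
          dir <- dir / sqrt(sum(dir^2))
          nxt <- pts[nrow(pts), ] + params$step_len * dir
          if (any(nxt < margin) || any(nxt > extent - margin)) break
          pts <- rbind(pts, nxt)
          len <- len + params$step_len
          if (runif(1) < params$branch_prob * params$step_len) {
            bd <- dir + perp_unit(dir) * tan(runif(1, 0.6, 1.2))
            bd <- bd / sqrt(sum(bd^2))
            stack[[length(stack) + 1L]] <-
              list(pos = nxt, dir = bd, r = max(1.5, tr$r * runif(1, 0.7, 1)),
                   spawn = nxt)
          }
        }
        if (nrow(pts) >= 2L) {
          edges[[length(edges) + 1L]] <-
            list(points = unname(pts), radius = rep(tr$r, nrow(pts)))
          total <- total + len
          # a bifurcation exists only if the child actually grew
          if (!is.null(tr$spawn)) branch_nodes <- rbind(branch_nodes, tr$spawn)
        }
      }
    }
    if (!length(edges))
      stop("volume too small to host any vessel at the requested calibers")
    vessel_network(edges, branch_nodes = branch_nodes, extent = extent)
  })
}

#' Place somata with a known attached fraction
#'
#' Places `round(attached_fraction * n_somata)` somata directly against a
#' vessel wall (wall gap <= `attach_gap_max` µm) and the remainder clearly
#' detached (wall gap > `detach_min_gap` µm), with no soma-soma overlap and a
#' placement density increasing with cortical depth per `depth_gradient`.
#' Attached somata are recorded with the host-vessel geometry needed to
#' render the wall-following cap.
#'
#' @param network a [vessel_network()].
#' @param params a [phantom_params()].
#' @return list with `somata` (ground-truth data frame: id, coordinates,
#'   radius, attached flag, true wall gap, host vessel diameter, bifurcation
#'   flag) and `attach_info` (per-soma rendering geometry).
#' @export
place_somata <- function(network, params) {
  validate_phantom_params(params)
  if (!length(network$edges)) stop("vessel network is empty")
  if (params$n_somata < 1L) stop("n_somata must be >= 1")
  extent <- network$extent %||% (params$volume_shape * params$voxel_size)
  dax <- params$depth_axis
  n <- params$n_somata
  n_att <- round(params$attached_fraction * n)

  with_seed(sub_seed(params$seed, 2L), {
    edge_len <- vapply(network$edges, function(e)
      sum(sqrt(rowSums(diff(e$points)^2))), numeric(1))
    placed <- list()
    attach_info <- list()
    centers <- matrix(numeric(0), 0, 3)
    radii <- numeric(0)

    ok_overlap <- function(center, R) {
      if (!nrow(centers)) return(TRUE)
      d <- sqrt(colSums((t(centers) - center)^2))
      all(d > radii + R + 2)          # 2 µm clearance so blobs never merge
    }
    draw_radius <- function()
      max(1.5, rnorm(1, params$soma_radius[[1]],
                     if (length(params$soma_radius) > 1)
                       params$soma_radius[[2]] else 0))
    gmax <- depth_weight(1, params$depth_gradient)

    place_one <- function(attached) {
      for (try in seq_len(400L)) {
        R <- draw_radius()
        if (identical(params$placement, "random")) {
          # unconstrained with respect to the vasculature: the scene used to
          # calibrate the chance-association null (somata may even straddle
          # vessels, exactly as a mirrored channel would)
          center <- (R + 1) + runif(3) * (extent - 2 * (R + 1))
          u <- center[dax] / extent[dax]
          if (runif(1) > depth_weight(u, params$depth_gradient) / gmax) next
          if (!ok_overlap(center, R)) next
          nv <- nearest_vessel(matrix(center, 1, 3), network)
          gap <- nv$surface_dist - R
          return(list(center = center, R = R, attached = isTRUE(gap <= 0.1),
                      true_gap = gap, host_diam = 2 * nv$radius, info = NULL))
        }
        if (attached) {
          ei <- sample.int(length(network$edges), 1L, prob = pmax(edge_len, 1e-9))
          e <- network$edges[[ei]]
          if (nrow(e$points) < 2L) next
          si <- sample.int(nrow(e$points) - 1L, 1L)
          tt <- runif(1)
          cp <- e$points[si, ] + tt * (e$points[si + 1L, ] - e$points[si, ])
          rv <- e$radius[si] + tt * (e$radius[si + 1L] - e$radius[si])
          axis <- e$points[si + 1L, ] - e$points[si, ]
          axis <- axis / sqrt(sum(axis^2))
          phi <- runif(1, 0, 2 * pi)
          pu <- perp_unit(axis)
          pv <- cross3(axis, pu)
          dirp <- cos(phi) * pu + sin(phi) * pv
          gap <- runif(1, 0, params$attach_gap_max)
          D <- rv + gap + R * cos(params$cap_angle)
          center <- cp + dirp * D
          if (any(center < R + 1) || any(center > extent - R - 1)) next
          u <- center[dax] / extent[dax]
          if (runif(1) > depth_weight(u, params$depth_gradient) / gmax) next
          if (!ok_overlap(center, R)) next
          # must not penetrate any *other* vessel
          others <- nearest_vessel(matrix(center, 1, 3), network)
          if (others$edge != ei && others$surface_dist < R * 0.8) next
          info <- list(host_edge = ei, host_segment = si,
                       contact_point = cp + dirp * (rv + gap),
                       centerline_point = cp, gap = gap, host_radius = rv)
          return(list(center = center, R = R, attached = TRUE,
                      true_gap = gap, host_diam = 2 * rv, info = info))
        } else {
          center <- (params$detach_min_gap + R + 1) +
            runif(3) * (extent - 2 * (params$detach_min_gap + R + 1))
          if (any(!is.finite(center))) next
          u <- center[dax] / extent[dax]
          if (runif(1) > depth_weight(u, params$depth_gradient) / gmax) next
          nv <- nearest_vessel(matrix(center, 1, 3), network)
          gap <- nv$surface_dist - R
          if (!is.finite(gap) || gap <= params$detach_min_gap) next
          if (!ok_overlap(center, R)) next
          return(list(center = center, R = R, attached = FALSE,
                      true_gap = gap, host_diam = 2 * nv$radius, info = NULL))
        }
      }
      NULL
    }

    flags <- c(rep(TRUE, n_att), rep(FALSE, n - n_att))
    for (i in seq_len(n)) {
      s <- place_one(flags[i])
      if (is.null(s))
        stop("could not place soma ", i, " without overlap after bounded ",
             "retries; achieved ", length(placed), " of ", n)
      placed[[i]] <- s
      attach_info[i] <- list(s$info)  # may be NULL for detached somata
      centers <- rbind(centers, s$center)
      radii <- c(radii, s$R)
    }

    at_bif <- vapply(seq_len(n), function(i) {
      if (!nrow(network$branch_nodes)) return(FALSE)
      d <- sqrt(colSums((t(network$branch_nodes) - placed[[i]]$center)^2))
      any(d <= placed[[i]]$R + 5)
    }, logical(1))

    somata <- data.frame(
      id = seq_len(n),
      c1 = centers[, 1], c2 = centers[, 2], c3 = centers[, 3],
      radius = radii,
      attached = vapply(placed, `[[`, logical(1), "attached"),
      true_gap = vapply(placed, `[[`, numeric(1), "true_gap"),
      host_vessel_diameter = vapply(placed, `[[`, numeric(1), "host_diam"),
      at_bifurcation = at_bif)
    list(somata = somata, attach_info = attach_info)
  })
}

#' Render a phantom scene into a multi-channel volume
#'
#' Image-formation model: the vasculature channel is a filled tube label,
#' wall markers are Gaussian shells at their configured offsets inward from
#' the soma-facing wall, somata are membrane-weighted spheres (attached
#' somata wrap onto the host vessel over a spherical cap), myelin is a
#' depth-weighted filament texture, and the optional "aqp4" channel is a wall
#' shell with an intensity dip at contact sites. The scene is then blurred
#' with a Gaussian PSF and corrupted with Poisson shot noise plus Gaussian
#' read noise. Deterministic for a fixed seed; intensities are non-negative.
#'
#' @param network a [vessel_network()].
#' @param somata result of [place_somata()] (or NULL for a cell-free scene).
#' @param params a [phantom_params()].
#' @return a [volume()]; ground-truth myelin occupancy per depth bin (before
#'   blur and noise) is attached as attribute `"myelin_truth"`.
#' @export
render_volume <- function(network, somata, params) {
  validate_phantom_params(params)
  shp <- params$volume_shape
  vx <- params$voxel_size
  extent <- shp * vx
  chans <- params$channels
  dimv <- as.integer(shp)
  nvox <- prod(dimv)
  arr <- array(0, c(shp, length(chans)))
  inplane <- min(vx)
  # ridge widths never drop below what the voxel grid can represent:
  # sub-voxel ridges alias (peak positions would quantize to voxel centers)
  shell_w <- max(0.08, 0.8 * inplane)
  rim_w <- max(0.2, 0.8 * inplane)
  myelin_truth <- NULL

  paint_channel <- function(name) {
    ch <- array(0, shp)
    if (name == "vessel") {
      for (e in network$edges)
        .paint_tube_cpp(ch, dimv, vx, e$points, e$radius, 0L, 0, inplane, 1)
    } else if (name %in% c("pericyte", "endothelial", "basement", "aqp4")) {
      off <- if (name == "aqp4") 0 else unname(params$marker_offsets[[name]])
      .paint_shell_cpp(ch, dimv, vx,
                       lapply(network$edges, `[[`, "points"),
                       lapply(network$edges, `[[`, "radius"),
                       off, shell_w, 1)
      if (name == "aqp4" && params$contact_dip > 0 && !is.null(somata)) {
        for (i in seq_len(nrow(somata$somata))) {
          info <- somata$attach_info[[i]]
          if (is.null(info)) next
          Rcap <- somata$somata$radius[i] * sin(params$cap_angle) + 0.5
          .scale_ball_cpp(ch, dimv, vx, info$contact_point, Rcap,
                          1 - params$contact_dip)
        }
      }
    } else if (name == "soma") {
      if (!is.null(somata)) {
        df <- somata$somata
        for (i in seq_len(nrow(df))) {
          info <- somata$attach_info[[i]]
          if (is.null(info)) {
            clip <- matrix(numeric(0), 0, 3); cr <- numeric(0); cg <- 0
          } else {
            e <- network$edges[[info$host_edge]]
            clip <- e$points; cr <- e$radius; cg <- info$gap
          }
          .paint_soma_cpp(ch, dimv, vx, c(df$c1[i], df$c2[i], df$c3[i]),
                          df$radius[i], 0.2, 1, rim_w, inplane,
                          clip, cr, cg)
        }
      }
    } else if (name == "myelin") {
      scale_f <- if (!is.null(somata) && !is.null(attr(somata, "myelin_scale")))
        attr(somata, "myelin_scale") else 1
      fil_r <- 0.3
      fil_len <- 10
      n_fil <- max(0L, round(scale_f * params$myelin_density * prod(extent) /
                               (pi * fil_r^2 * fil_len)))
      dax <- params$depth_axis
      gmax <- depth_weight(1, params$depth_gradient)
      made <- 0L
      while (made < n_fil) {
        p0 <- runif(3) * extent
        u <- p0[dax] / extent[dax]
        if (runif(1) > depth_weight(u, params$depth_gradient) / gmax) next
        d <- runit3()
        p1 <- pmin(pmax(p0 + d * runif(1, 5, 15), 0), extent)
        .paint_tube_cpp(ch, dimv, vx, rbind(p0, p1), rep(fil_r, 2), 0L, 0,
                        inplane, 1)
        made <- made + 1L
      }
      # ground-truth occupancy per 25 µm depth bin, before blur/noise
      nb <- ceiling(extent[dax] / 25)
      occ <- numeric(nb)
      pos <- ch > 0.5
      dd <- dim(pos)[dax]
      bin_of <- findInterval((seq_len(dd) - 0.5) * vx[dax],
                             seq(0, nb * 25, 25), rightmost.closed = TRUE)
      for (b in seq_len(nb)) {
        sel <- which(bin_of == b)
        if (!length(sel)) next
        occ[b] <- mean(if (dax == 1L) pos[sel, , ] else
                       if (dax == 2L) pos[, sel, ] else pos[, , sel])
      }
      myelin_truth <<- data.frame(bin_lo = seq(0, by = 25, length.out = nb),
                                  bin_hi = seq(25, by = 25, length.out = nb),
                                  occupancy = occ)
    } else stop("unknown channel: ", name)
    ch
  }

  with_seed(sub_seed(params$seed, 3L), {
    for (ci in seq_along(chans)) arr[, , , ci] <- paint_channel(chans[ci])
  })

  sig_vox <- params$psf_sigma / vx
  if (any(sig_vox > 0)) {
    for (ci in seq_along(chans)) {
      ch <- array(arr[, , , ci], shp)
      .gauss_blur3_cpp(ch, dimv, sig_vox)
      arr[, , , ci] <- ch
    }
  }

  ps <- unname(params$noise[[1]])
  gs <- if (length(params$noise) > 1) unname(params$noise[[2]]) else 0
  if (ps > 0 || gs > 0) {
    with_seed(sub_seed(params$seed, 4L), {
      v <- as.numeric(arr)
      if (ps > 0) v <- rpois(length(v), ps * v) / ps
      if (gs > 0) v <- v + rnorm(length(v), sd = gs)
      arr <- array(pmax(v, 0), dim(arr))
    })
  }

  out <- volume(arr, vx, chans, depth_axis = params$depth_axis,
                provenance = list(generator = "perivasc phantom",
                                  seed = params$seed))
  attr(out, "myelin_truth") <- myelin_truth
  out
}

#' Simulate a complete phantom: network, somata, rendered volume, truth
#'
#' @param params a [phantom_params()].
#' @return list of class `pv_phantom` with `volume`, `truth` (somata data
#'   frame, network, myelin occupancy per depth bin) and `params`.
#' @export
simulate_phantom <- function(params) {
  network <- generate_vessel_network(params)
  somata <- place_somata(network, params)
  vol <- render_volume(network, somata, params)
  structure(list(volume = vol,
                 truth = list(somata = somata$somata, network = network,
                              attach_info = somata$attach_info,
                              myelin = attr(vol, "myelin_truth")),
                 params = params),
            class = "pv_phantom")
}

#' Demyelination / remyelination scenario
#'
#' Scales the soma population of a baseline phantom by a survival fraction,
#' uniformly across the attached and detached pools, so the true
#' vessel-attached proportion is unchanged up to rounding (cuprizone
#' demyelination removes oligodendrocytes independently of their vascular
#' association). The myelin texture is scaled by the same fraction.
#'
#' @param params a [phantom_params()] describing the baseline scene.
#' @param survival_fraction fraction of somata surviving, in [0, 1].
#' @return a `pv_phantom` for the scaled scene (same seed: `survival_fraction
#'   = 1` reproduces the baseline exactly).
#' @export
demyelination_scenario <- function(params, survival_fraction) {
  if (survival_fraction < 0 || survival_fraction > 1)
    stop("survival_fraction must lie in [0, 1]")
  network <- generate_vessel_network(params)
  somata <- place_somata(network, params)
  df <- somata$somata
  keep <- with_seed(sub_seed(params$seed, 5L), {
    ia <- df$id[df$attached]
    id <- df$id[!df$attached]
    sort(c(if (length(ia)) sample(ia, round(survival_fraction * length(ia))),
           if (length(id)) sample(id, round(survival_fraction * length(id)))))
  })
  sel <- df$id %in% keep
  somata2 <- list(somata = df[sel, , drop = FALSE],
                  attach_info = somata$attach_info[sel])
  somata2$somata$id <- seq_len(nrow(somata2$somata))
  attr(somata2, "myelin_scale") <- survival_fraction
  vol <- render_volume(network, somata2, params)
  structure(list(volume = vol,
                 truth = list(somata = somata2$somata, network = network,
                              attach_info = somata2$attach_info,
                              myelin = attr(vol, "myelin_truth")),
                 params = params,
                 survival_fraction = survival_fraction),
            class = "pv_phantom")
}
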
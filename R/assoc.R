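#' Line profile through a soma-vessel contact site
#'
#' Casts a line from the soma centroid through the nearest centerline point
#' of the vessel network and past the far vessel wall, and samples every
#' channel by trilinear interpolation in physical coordinates at a uniform
#' spacing of half the smallest voxel size. This automates the manual
#' line-tool measurement across the contact site.
#'
#' Nearest vessel = smallest distance from the centroid to a tube surface;
#' exact ties are broken towards the lowest edge id. If no vessel surface
#' lies within `search_radius` the soma is reported as non-associated and no
#' profile is produced (NULL).
#'
#' @param vol a [volume()].
#' @param soma a `pv_soma` (or a list with a `centroid` field).
#' @param network a [vessel_network()].
#' @param search_radius µm; default 20.
#' @param margin extra length (µm) past the far vessel wall.
#' @return a `pv_profile` (positions in µm from the centroid, per-channel
#'   intensity matrix, endpoints, nearest-vessel info), or NULL.
#' @export
contact_line <- function(vol, soma, network, search_radius = 20,
                         margin = 3) {
  if (!length(network$edges)) return(NULL)
  centroid <- soma$centroid
  nv <- nearest_vessel(matrix(centroid, 1, 3), network)
  if (!is.finite(nv$surface_dist) || nv$surface_dist > search_radius)
    return(NULL)
  u <- nv$point[1, ] - centroid
  L <- sqrt(sum(u^2))
  if (L < 1e-9) return(NULL)  # centroid on the centerline: degenerate
  u <- u / L
  t_end <- L + nv$radius + margin
  step <- min(vol$voxel_size) / 4
  tt <- seq(0, t_end, by = step)
  if (length(tt) < 16L) tt <- seq(0, t_end, length.out = 16L)
  pts <- matrix(centroid, length(tt), 3, byrow = TRUE) + outer(tt, u)
  d <- dim(vol$data)
  ch <- matrix(NA_real_, length(tt), length(vol$channel_names),
               dimnames = list(NULL, vol$channel_names))
  for (ci in seq_along(vol$channel_names))
    ch[, ci] <- .trilinear4_cpp(vol$data, as.integer(d), vol$voxel_size,
                                pts, ci)
  structure(list(position = tt, channels = ch,
                 endpoints = rbind(centroid, pts[length(tt), ]),
                 direction = u, nearest = nv,
                 wall_position = L - nv$radius),  # expected near-wall crossing
            class = "pv_profile")
}

#' Peak-to-peak distance between two channels of a line profile
#'
#' Locates the intensity maximum of the cell channel, then the local maximum
#' of the vessel-marker channel closest to it (the near-wall shell), refines
#' both to sub-sample precision with a three-point parabolic fit, and
#' returns the absolute distance between the two fluorescence peaks in µm.
#' Sub-sample refinement reduces voxel-quantization bias and can be turned
#' off to mimic pixel-resolution maxima.
#'
#' @param profile a `pv_profile` from [contact_line()].
#' @param soma_channel,vessel_channel channel names.
#' @param refine logical; parabolic sub-sample refinement (default TRUE).
#' @param window half-width (µm) of the search window around the contact
#'   site (the near-wall crossing recorded in the profile); NULL searches
#'   the whole profile.
#' @return distance in µm.
#' @export
peak_distance <- function(profile, soma_channel, vessel_channel,
                          refine = TRUE, window = 3) {
  pos <- profile$position
  for (chn in c(soma_channel, vessel_channel))
    if (!chn %in% colnames(profile$channels))
      stop("channel '", chn, "' not present in the profile")
  ys <- profile$channels[, soma_channel]
  yv <- profile$channels[, vessel_channel]
  if (diff(range(ys)) < .Machine$double.eps)
    stop("flat profile in channel '", soma_channel, "': no unique maximum")
  if (diff(range(yv)) < .Machine$double.eps)
    stop("flat profile in channel '", vessel_channel, "': no unique maximum")
  step <- pos[2] - pos[1]
  wall_near <- soma_near <- rep(TRUE, length(pos))
  if (!is.null(window) && !is.null(profile$wall_position)) {
    # the wall-marker peak must sit near the wall crossing; the cell peak
    # sits anywhere between the centroid and just past the wall (a detached
    # soma peaks far before the wall — that distance is the measurement)
    wall_near <- abs(pos - profile$wall_position) <= window
    soma_near <- pos <= profile$wall_position + window
  }
  if (!any(wall_near)) wall_near <- rep(TRUE, length(pos))
  if (!any(soma_near)) soma_near <- rep(TRUE, length(pos))
  pick_peak <- function(y, near, anchor = NULL) {
    cand <- local_maxima(y)
    cand <- cand[near[cand] & y[cand] >= 0.2 * max(y[near])]
    if (!length(cand)) cand <- which(near)[which.max(y[near])]
    i <- if (is.null(anchor)) cand[which.max(y[cand])]
         else cand[which.min(abs(pos[cand] - anchor))]
    pos[i] + if (refine) parabolic_offset(y, i) * step else 0
  }
  ps <- pick_peak(ys, soma_near)
  pv <- pick_peak(yv, wall_near, anchor = ps)
  abs(pv - ps)
}

#' Classify a soma as vasculature-associated
#'
#' A cell body is vasculature-associated when its peak-to-peak distance from
#' the blood-vessel wall is less than or equal to the threshold (1 µm,
#' boundary inclusive).
#'
#' @param distance peak distance in µm (NA treated as not associated).
#' @param threshold µm, default 1.
#' @return logical flag.
#' @export
classify_vol <- function(distance, threshold = 1.0) {
  if (any(is.finite(distance) & distance < 0)) stop("distance must be >= 0")
  !is.na(distance) & distance <= threshold
}

#' Diameter of the vessel associated with a soma
#'
#' Twice the median centerline radius of the nearest edge over the segment
#' points lying within `search_radius` (default 20 µm) of the soma centroid.
#'
#' @param soma a `pv_soma`.
#' @param network a [vessel_network()].
#' @param search_radius µm.
#' @return diameter in µm, or NA if no vessel lies within the radius.
#' @export
vessel_diameter_at <- function(soma, network, search_radius = 20) {
  if (!length(network$edges)) return(NA_real_)
  nv <- nearest_vessel(matrix(soma$centroid, 1, 3), network)
  if (!is.finite(nv$surface_dist) || nv$surface_dist > search_radius)
    return(NA_real_)
  e <- network$edges[[nv$edge]]
  d <- sqrt(colSums((t(e$points) - soma$centroid)^2))
  sel <- d <= search_radius
  if (!any(sel)) sel <- which.min(d)
  2 * median(e$radius[sel])
}

#' Vessel caliber category
#'
#' Diameter < 8 µm: capillary; 8 to 15 µm (inclusive on both bounds):
#' intermediate (precapillary arterioles or postcapillary venules);
#' > 15 µm: large (arterioles/venules and arteries/veins).
#'
#' @param diameter µm, > 0 (NA allowed, returns NA).
#' @return factor level among capillary, intermediate, large.
#' @export
categorize_vessel <- function(diameter) {
  lv <- c("capillary", "intermediate", "large")
  out <- rep(NA_character_, length(diameter))
  ok <- !is.na(diameter)
  if (any(diameter[ok] <= 0)) stop("diameter must be positive")
  out[ok & diameter < 8] <- "capillary"
  out[ok & diameter >= 8 & diameter <= 15] <- "intermediate"
  out[ok & diameter > 15] <- "large"
  factor(out, levels = lv)
}

#' Is a soma located at a vascular branching site?
#'
#' TRUE when a branch node of the centerline network lies within
#' (soma radius + tolerance) of the soma centroid.
#'
#' @param soma a `pv_soma` (uses `radius_equiv`).
#' @param network a [vessel_network()].
#' @param tolerance µm, default 5.
#' @return logical.
#' @export
at_bifurcation <- function(soma, network, tolerance = 5) {
  if (!nrow(network$branch_nodes)) return(FALSE)
  d <- sqrt(colSums((t(network$branch_nodes) - soma$centroid)^2))
  any(d <= (soma$radius_equiv %||% 0) + tolerance)
}

#' Soma-vessel contact area
#'
#' Area of the soma-mesh faces whose distance to the vessel-wall surface is
#' at most `contact_distance`. The soma is always the primary surface (its
#' faces are classified, never the vessel's), which avoids overestimating
#' the contact. The vessel may be given as a centerline network (analytic
#' tube surfaces) or as a distance function over points.
#'
#' @param soma a `pv_soma` with a watertight mesh.
#' @param vessel a [vessel_network()] or a function(points) returning the
#'   distance of each point to the vessel surface.
#' @param contact_distance µm, default 0.1 (below optical resolution, above
#'   mesh jitter).
#' @return list with `area` (µm²), `fraction` of the soma surface, and the
#'   total soma `surface_area`.
#' @export
contact_area <- function(soma, vessel, contact_distance = 0.1) {
  mesh <- soma$mesh
  if (!mesh_is_watertight(mesh))
    stop("soma mesh is not watertight; re-segment the soma before ",
         "contact-area measurement")
  cent <- mesh_face_centroids(mesh)
  areas <- mesh_face_areas(mesh)
  dist <- if (inherits(vessel, "pv_network")) {
    nv <- nearest_vessel(cent, vessel)
    abs(nv$surface_dist)
  } else if (is.function(vessel)) {
    abs(vessel(cent))
  } else stop("vessel must be a pv_network or a distance function")
  area <- sum(areas[dist <= contact_distance])
  total <- sum(areas)
  list(area = area, fraction = if (total > 0) area / total else 0,
       surface_area = total)
}

#' Wall-marker intensity at and away from a contact site
#'
#' Mean marker intensity in a wall-hugging ROI at the soma contact site and
#' in equally sized control ROIs on the same vessel at least `min_separation`
#' µm away (paired design: contact vs elsewhere on the same vessel).
#'
#' @param vol a [volume()].
#' @param marker_channel channel name (e.g. an AQP4-like wall marker).
#' @param soma a `pv_soma`.
#' @param network a [vessel_network()].
#' @param n_control_sites number of control ROIs requested.
#' @param roi_radius in-wall ROI half-extent along the vessel (µm).
#' @param min_separation minimum arc distance from the contact site (µm).
#' @return list with `contact` (mean intensity), `control` (vector),
#'   `ratio` = contact / mean(control).
#' @export
intensity_at_contact <- function(vol, marker_channel, soma, network,
                                 n_control_sites = 3L, roi_radius = 1,
                                 min_separation = 10) {
  nv <- nearest_vessel(matrix(soma$centroid, 1, 3), network)
  if (!is.finite(nv$surface_dist)) stop("no vessel near the soma")
  e <- network$edges[[nv$edge]]
  arr <- get_channel(vol, marker_channel)
  d3 <- as.integer(dim(arr))

  wall_ring_mean <- function(cp, axis_dir, r, arc_halfwidth, sector_dir = NULL,
                             sector_cos = NULL) {
    pu <- perp_unit(axis_dir)
    pv <- cross3(axis_dir, pu)
    ang <- seq(0, 2 * pi, length.out = 49L)[-49L]
    long <- seq(-arc_halfwidth, arc_halfwidth, length.out = 5L)
    pts <- NULL
    for (dl in long) {
      ring <- t(vapply(ang, function(a)
        cp + dl * axis_dir + r * (cos(a) * pu + sin(a) * pv), numeric(3)))
      pts <- rbind(pts, ring)
    }
    if (!is.null(sector_dir)) {
      rel <- sweep(pts, 2, cp)
      rel <- rel - outer(rel %*% axis_dir, axis_dir)[, , 1]
      nn <- sqrt(rowSums(rel^2))
      cosang <- (rel %*% sector_dir) / pmax(nn, 1e-9)
      pts <- pts[cosang >= sector_cos, , drop = FALSE]
    }
    ext <- d3 * vol$voxel_size
    inside <- pts[, 1] > 0 & pts[, 2] > 0 & pts[, 3] > 0 &
      pts[, 1] < ext[1] & pts[, 2] < ext[2] & pts[, 3] < ext[3]
    pts <- pts[inside, , drop = FALSE]
    if (!nrow(pts)) return(NA_real_)
    mean(.trilinear_cpp(arr, d3, vol$voxel_size, pts))
  }

  # arc-length position of each centerline point
  seglen <- sqrt(rowSums(diff(e$points)^2))
  arc <- c(0, cumsum(seglen))
  si <- nv$segment
  arc0 <- arc[si]
  # local axis at the contact
  a_dir <- e$points[min(si + 1L, nrow(e$points)), ] - e$points[si, ]
  a_dir <- a_dir / max(sqrt(sum(a_dir^2)), 1e-9)
  toward <- soma$centroid - nv$point[1, ]
  toward <- toward - sum(toward * a_dir) * a_dir
  toward <- toward / max(sqrt(sum(toward^2)), 1e-9)

  contact <- wall_ring_mean(nv$point[1, ], a_dir, nv$radius, roi_radius,
                            sector_dir = toward, sector_cos = cos(pi / 3))

  controls <- numeric(0)
  offs <- min_separation * seq_len(n_control_sites)
  cand <- c(arc0 + offs, arc0 - offs)
  cand <- cand[cand >= 0 & cand <= max(arc)]
  for (a in cand) {
    if (length(controls) >= n_control_sites) break
    ci <- findInterval(a, arc, rightmost.closed = TRUE)
    ci <- max(1L, min(ci, nrow(e$points) - 1L))
    tloc <- (a - arc[ci]) / max(seglen[ci], 1e-9)
    cp <- e$points[ci, ] + tloc * (e$points[ci + 1L, ] - e$points[ci, ])
    rr <- e$radius[ci] + tloc * (e$radius[ci + 1L] - e$radius[ci])
    adir <- e$points[ci + 1L, ] - e$points[ci, ]
    adir <- adir / max(sqrt(sum(adir^2)), 1e-9)
    m <- wall_ring_mean(cp, adir, rr, roi_radius)
    if (is.finite(m)) controls <- c(controls, m)
  }
  if (length(controls) < n_control_sites)
    warning("vessel too short for ", n_control_sites,
            " control sites; using ", length(controls))
  list(contact = contact, control = controls,
       ratio = contact / mean(controls))
}

#' Per-soma association records
#'
#' Runs the association measurements for every segmented soma: marker-wise
#' peak distances, vOL classification (on the minimum marker distance),
#' vessel diameter and caliber category, bifurcation flag and (optionally)
#' contact area. Somata touching the volume border are excluded from the
#' records (flagged upstream) since their geometry may be truncated.
#'
#' @param vol a [volume()].
#' @param network a [vessel_network()].
#' @param somata list of `pv_soma` from [segment_somata()].
#' @param config a [pipeline_config()].
#' @return data.frame with one row per included soma.
#' @export
associate_somata <- function(vol, network, somata, config = pipeline_config()) {
  markers <- intersect(config$marker_channels, vol$channel_names)
  if (!length(markers))
    stop("no marker channel available (looked for: ",
         paste(config$marker_channels, collapse = ", "), ")")
  somata <- Filter(function(s) !isTRUE(s$border), somata)
  rows <- lapply(somata, function(s) {
    rec <- list(soma_id = s$id,
                c1 = s$centroid[1], c2 = s$centroid[2], c3 = s$centroid[3],
                volume = s$volume, surface_area = s$surface_area)
    prof <- contact_line(vol, s, network,
                         search_radius = config$search_radius)
    dists <- setNames(rep(NA_real_, length(markers)), markers)
    if (!is.null(prof)) {
      for (m in markers) {
        dm <- try(peak_distance(prof, config$soma_channel, m,
                                refine = config$refine_peaks), silent = TRUE)
        if (!inherits(dm, "try-error")) dists[m] <- dm
      }
    }
    for (m in markers) rec[[paste0("d_", m)]] <- dists[[m]]
    dmin <- if (all(is.na(dists))) NA_real_ else min(dists, na.rm = TRUE)
    rec$distance <- dmin
    rec$is_vol <- classify_vol(dmin, config$association_threshold)
    diam <- vessel_diameter_at(s, network, config$search_radius)
    rec$vessel_diameter <- diam
    rec$vessel_category <- as.character(categorize_vessel(diam))
    rec$at_bifurcation <- at_bifurcation(s, network,
                                         config$bifurcation_tolerance)
    if (isTRUE(config$measure_contact_area) && rec$is_vol &&
        length(network$edges)) {
      ca <- try(contact_area(s, network, config$contact_distance),
                silent = TRUE)
      if (!inherits(ca, "try-error")) {
        rec$contact_area <- ca$area
        rec$contact_fraction <- ca$fraction
      } else {
        rec$contact_area <- NA_real_
        rec$contact_fraction <- NA_real_
      }
    } else {
      rec$contact_area <- NA_real_
      rec$contact_fraction <- NA_real_
    }
    as.data.frame(rec, stringsAsFactors = FALSE)
  })
  if (!length(rows)) {
    return(data.frame(soma_id = integer(0)))
  }
  do.call(rbind, rows)
}
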
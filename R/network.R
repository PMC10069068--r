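#' Vessel centerline network
#'
#' A vessel network is a set of centerline polylines ("edges") with a radius
#' at every polyline point, plus the branch nodes (centerline points of
#' degree >= 3). Coordinates are micrometres in volume axis order.
#'
#' @param edges list; each element a list with `points` (n x 3 matrix, µm)
#'   and `radius` (length-n vector, µm > 0).
#' @param branch_nodes m x 3 matrix of branch-node coordinates (µm); may have
#'   zero rows.
#' @param mask optional binary voxel mask the network was extracted from.
#' @param extent optional length-3 physical extent (µm).
#' @return an object of class `pv_network`.
#' @export
vessel_network <- function(edges, branch_nodes = NULL, mask = NULL,
                           extent = NULL) {
  for (e in edges) {
    stopifnot(is.matrix(e$points), ncol(e$points) == 3L,
              length(e$radius) == nrow(e$points))
    if (any(e$radius <= 0)) stop("all centerline radii must be > 0")
  }
  if (is.null(branch_nodes)) branch_nodes <- matrix(numeric(0), 0, 3)
  structure(list(edges = edges, branch_nodes = branch_nodes, mask = mask,
                 extent = extent),
            class = "pv_network")
}

#' @export
print.pv_network <- function(x, ...) {
  cat("<pv_network> ", length(x$edges), " edge(s), ",
      nrow(x$branch_nodes), " branch node(s), total length ",
      round(network_length(x), 1), " µm\n", sep = "")
  invisible(x)
}

#' Total centerline length of a network (µm)
#' @param network a [vessel_network()].
#' @export
network_length <- function(network) {
  sum(vapply(network$edges, function(e) {
    if (nrow(e$points) < 2L) return(0)
    sum(sqrt(rowSums(diff(e$points)^2)))
  }, numeric(1)))
}

# Distance from points to the nearest vessel *surface* over all edges.
# Returns a list with, per point: surface_dist (negative inside a tube),
# axis_dist, local radius, edge id, segment index and the nearest centerline
# point. Exact ties between edges are broken towards the lowest edge id
# (edges are scanned in id order with a strict improvement test).
nearest_vessel <- function(points, network) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  n <- nrow(points)
  best <- list(surface_dist = rep(Inf, n), axis_dist = rep(NA_real_, n),
               radius = rep(NA_real_, n), edge = rep(NA_integer_, n),
               segment = rep(NA_integer_, n),
               point = matrix(NA_real_, n, 3))
  for (ei in seq_along(network$edges)) {
    e <- network$edges[[ei]]
    if (nrow(e$points) < 2L) next
    r <- .tube_surface_dist_cpp(points, e$points, e$radius)
    imp <- r$surface_dist < best$surface_dist
    if (any(imp)) {
      best$surface_dist[imp] <- r$surface_dist[imp]
      best$axis_dist[imp] <- r$axis_dist[imp]
      best$radius[imp] <- r$radius[imp]
      best$edge[imp] <- ei
      best$segment[imp] <- r$segment[imp]
      best$point[imp, ] <- r$point[imp, , drop = FALSE]
    }
  }
  best
}

# Minimum distance from a point to the surface of every tube in the network
# (negative if inside any tube).
vessel_surface_distance <- function(points, network) {
  nearest_vessel(points, network)$surface_dist
}

# convenience constructor: one or more explicit tubes
# tubes: list of list(start, end, radius) in µm
tube_network <- function(tubes, extent = NULL) {
  edges <- lapply(tubes, function(tb) {
    p0 <- as.numeric(tb$start); p1 <- as.numeric(tb$end)
    L <- sqrt(sum((p1 - p0)^2))
    n <- max(2L, ceiling(L / 2))
    tt <- seq(0, 1, length.out = n + 1L)
    list(points = outer(tt, p1 - p0) + matrix(p0, n + 1L, 3, byrow = TRUE),
         radius = rep(as.numeric(tb$radius), n + 1L))
  })
  # branch nodes: endpoints shared by >= 3 tube ends
  ends <- do.call(rbind, lapply(tubes, function(tb) rbind(tb$start, tb$end)))
  key <- apply(round(ends, 6), 1, paste, collapse = "/")
  tab <- table(key)
  bn_keys <- names(tab)[tab >= 3L]
  bn <- ends[match(bn_keys, key), , drop = FALSE]
  vessel_network(edges, branch_nodes = bn, extent = extent)
}
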
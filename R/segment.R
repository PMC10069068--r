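#' Threshold a channel into a despeckled binary mask
#'
#' Intensity threshold (automatic Otsu by default, or a fixed value recorded
#' by the caller) followed by removal of small connected components —
#' positive outliers from acquisition noise. Despeckling is idempotent.
#'
#' @param vol a [volume()].
#' @param channel channel name.
#' @param method "otsu" or "fixed".
#' @param threshold fixed threshold (required for `method = "fixed"`).
#' @param min_component_size components with fewer voxels are removed
#'   (default 3, the "< 3 pixels" outlier rule).
#' @param connectivity 6 or 26 (3D).
#' @return logical 3D array with attributes `voxel_size` and `threshold`.
#' @export
threshold_mask <- function(vol, channel, method = c("otsu", "fixed"),
                           threshold = NULL, min_component_size = 3L,
                           connectivity = 26L) {
  method <- match.arg(method)
  ch <- get_channel(vol, channel)
  if (all(ch == 0)) {
    warning("channel '", channel, "' is all zero: returning an empty mask")
    mask <- array(FALSE, dim(ch))
    attr(mask, "voxel_size") <- vol$voxel_size
    attr(mask, "threshold") <- NA_real_
    return(mask)
  }
  thr <- if (method == "fixed") {
    if (is.null(threshold)) stop("method 'fixed' requires a threshold")
    threshold
  } else otsu_threshold(ch)
  mask <- ch >= thr
  mask <- despeckle(mask, min_component_size, connectivity)
  attr(mask, "voxel_size") <- vol$voxel_size
  attr(mask, "threshold") <- thr
  mask
}

#' Remove connected components below a minimum size
#'
#' @param mask logical 3D array.
#' @param min_component_size minimum voxel count to keep.
#' @param connectivity 6 or 26.
#' @return logical array of the same shape (attributes preserved).
#' @export
despeckle <- function(mask, min_component_size = 3L, connectivity = 26L) {
  if (min_component_size <= 1L || !any(mask)) return(mask)
  at <- attributes(mask)
  lab <- .label3d_cpp(as.logical(mask), as.integer(dim(mask)),
                      as.integer(connectivity))
  sizes <- tabulate(lab)
  out <- array(mask & sizes[pmax(lab, 1L)] >= min_component_size, dim(mask))
  attributes(out) <- at
  out
}

#' Myelin occupancy within a planar ROI
#'
#' Fraction of positive pixels in a single z-plane rectangular ROI after
#' thresholding and removal of isolated 1x1 positive pixels, i.e. the myelin
#' density measure: myelin-positive area divided by ROI area. The default
#' ROI covers 1e4 µm².
#'
#' @param vol a [volume()].
#' @param channel myelin channel name.
#' @param roi list with `plane` (axis-1 index), `a2` and `a3` (µm ranges
#'   c(lo, hi) along axes 2 and 3). NULL uses a centered 100 x 100 µm square
#'   in the middle plane.
#' @param method,threshold threshold rule as in [threshold_mask()].
#' @return occupancy fraction in [0, 1].
#' @export
myelin_occupancy <- function(vol, channel, roi = NULL,
                             method = c("otsu", "fixed"), threshold = NULL) {
  method <- match.arg(method)
  ch <- get_channel(vol, channel)
  ext <- vol_extent(vol)
  if (is.null(roi)) {
    side <- min(100, ext[2], ext[3])
    roi <- list(plane = ceiling(dim(ch)[1] / 2),
                a2 = ext[2] / 2 + c(-side / 2, side / 2),
                a3 = ext[3] / 2 + c(-side / 2, side / 2))
  }
  v <- vol$voxel_size
  j <- which((seq_len(dim(ch)[2]) - 0.5) * v[2] >= roi$a2[1] &
               (seq_len(dim(ch)[2]) - 0.5) * v[2] <= roi$a2[2])
  k <- which((seq_len(dim(ch)[3]) - 0.5) * v[3] >= roi$a3[1] &
               (seq_len(dim(ch)[3]) - 0.5) * v[3] <= roi$a3[2])
  if (roi$plane < 1 || roi$plane > dim(ch)[1] || !length(j) || !length(k) ||
      roi$a2[1] < 0 || roi$a3[1] < 0 || roi$a2[2] > ext[2] ||
      roi$a3[2] > ext[3])
    stop("ROI lies outside the image")
  sl <- ch[roi$plane, j, k]
  dim(sl) <- c(length(j), length(k), 1L)
  if (all(sl == 0)) return(0)
  thr <- if (method == "fixed") {
    if (is.null(threshold)) stop("method 'fixed' requires a threshold")
    threshold
  } else otsu_threshold(sl)
  pos <- sl >= thr
  # remove isolated 1x1 pixels (components of size < 2, 8-connectivity)
  pos <- despeckle(pos, 2L, 26L)
  mean(pos)
}

#' Vascular density from a maximum-intensity projection
#'
#' Thresholds the maximum-intensity z-projection of the vasculature channel,
#' removes < 3 pixel outliers, and divides the positive (projected) area by
#' the ROI volume. The area-per-volume convention (µm²/µm³) of the source
#' measurement is kept as-is.
#'
#' @param vol a [volume()].
#' @param channel vasculature channel name.
#' @param roi list with `a2`, `a3` µm ranges (full z is always used); NULL
#'   uses the whole field.
#' @param method,threshold threshold rule as in [threshold_mask()].
#' @return density in µm² of projected vessel area per µm³.
#' @export
vascular_density <- function(vol, channel, roi = NULL,
                             method = c("otsu", "fixed"), threshold = NULL) {
  method <- match.arg(method)
  ch <- get_channel(vol, channel)
  ext <- vol_extent(vol)
  if (is.null(roi)) roi <- list(a2 = c(0, ext[2]), a3 = c(0, ext[3]))
  v <- vol$voxel_size
  j <- which((seq_len(dim(ch)[2]) - 0.5) * v[2] >= roi$a2[1] &
               (seq_len(dim(ch)[2]) - 0.5) * v[2] <= roi$a2[2])
  k <- which((seq_len(dim(ch)[3]) - 0.5) * v[3] >= roi$a3[1] &
               (seq_len(dim(ch)[3]) - 0.5) * v[3] <= roi$a3[2])
  if (!length(j) || !length(k)) stop("ROI lies outside the image")
  proj <- apply(ch[, j, k, drop = FALSE], c(2, 3), max)
  if (all(proj == 0)) return(0)
  thr <- if (method == "fixed") {
    if (is.null(threshold)) stop("method 'fixed' requires a threshold")
    threshold
  } else otsu_threshold(proj)
  pos <- proj >= thr
  dim(pos) <- c(dim(proj), 1L)
  pos <- despeckle(pos, 3L, 26L)
  area <- sum(pos) * v[2] * v[3]
  depth <- ext[1]
  area / (length(j) * v[2] * length(k) * v[3] * depth)
}

#' Extract a centerline network from a binary vessel mask
#'
#' Computes the anisotropic Euclidean distance transform and traces the
#' centerlines with a TEASAR-style algorithm: Dijkstra shortest paths whose
#' edge costs penalize leaving the distance-transform ridge are traced from
#' the farthest unconsumed voxel back to the growing skeleton, and the tube
#' volume around each traced path is consumed until the mask is covered.
#' Where a new path meets the skeleton, a branch node is recorded. Per-point
#' radii are read from the distance transform at the centerline (corrected
#' by half a voxel for the discrete surface offset); spurious twigs shorter
#' than `prune_len` are discarded.
#'
#' @param mask logical 3D array (vessel voxels), e.g. from
#'   [threshold_mask()].
#' @param voxel_size µm per voxel per axis.
#' @param prune_len minimum length (µm) for a side branch to be kept.
#' @return a [vessel_network()]; empty (with a warning) if the mask contains
#'   no tube-like component.
#' @export
extract_network <- function(mask, voxel_size = attr(mask, "voxel_size"),
                            prune_len = 5) {
  if (is.null(voxel_size)) stop("voxel_size is required")
  if (!any(mask)) {
    warning("empty mask: returning an empty network")
    return(vessel_network(list(), extent = dim(mask) * voxel_size))
  }
  d <- dim(mask)
  dimv <- as.integer(d)
  voxel_size <- as.numeric(voxel_size)
  # outside the imaged volume counts as background, so vessels clipped by
  # the stack border do not grow spurious medial surfaces on the cut face
  padm <- array(FALSE, d + 2L)
  padm[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- mask
  edtp <- .edt3d_cpp(padm, as.integer(d + 2L), voxel_size)
  edt <- edtp[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)]
  tp <- .teasar_paths_cpp(as.logical(mask), edt, dimv, voxel_size)
  if (!length(tp$paths)) {
    warning("no skeleton found: returning an empty network")
    return(vessel_network(list(), extent = d * voxel_size))
  }
  rmin <- 0.5 * min(voxel_size)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  mk_edge <- function(pm) {
    # per-point radius: local distance-transform ridge value (the traced
    # path may sit up to a voxel off the exact medial axis)
    emax <- rep(0, nrow(pm))
    for (oi in seq_len(nrow(offs))) {
      sh <- pm + matrix(offs[oi, ], nrow(pm), 3, byrow = TRUE)
      sh[, 1] <- pmin(pmax(sh[, 1], 1L), d[1])
      sh[, 2] <- pmin(pmax(sh[, 2], 1L), d[2])
      sh[, 3] <- pmin(pmax(sh[, 3], 1L), d[3])
      idx <- sh[, 1] + (sh[, 2] - 1L) * d[1] + (sh[, 3] - 1L) * d[1] * d[2]
      emax <- pmax(emax, edt[idx])
    }
    pts <- sweep(pm - 0.5, 2, voxel_size, "*")
    list(points = unname(pts),
         radius = pmax(emax - 0.25 * mean(voxel_size), rmin))
  }
  edges <- lapply(tp$paths, mk_edge)
  lens <- vapply(edges, function(e)
    if (nrow(e$points) < 2) 0 else sum(sqrt(rowSums(diff(e$points)^2))),
    numeric(1))
  attach <- tp$attach_owner  # 0-based owner path id, -1 = trunk
  # keep trunks and side branches of sufficient length; side branches that
  # never leave their host tube are medial-axis artifacts (end caps, ridge
  # plateaus of wide vessels), not vessels
  keep <- attach < 0L | lens >= prune_len
  # iterate: dropping one spur can expose another that only "escaped" into it
  repeat {
    dropped <- FALSE
    for (i in which(keep & attach >= 0L)) {
      inside <- rep(Inf, nrow(edges[[i]]$points))
      for (j in which(keep)) {
        if (j == i) next
        sd <- .tube_surface_dist_cpp(edges[[i]]$points, edges[[j]]$points,
                                     edges[[j]]$radius)$surface_dist
        inside <- pmin(inside, sd)
      }
      if (max(inside) < 2 * max(voxel_size)) {
        keep[i] <- FALSE
        dropped <- TRUE
      }
    }
    if (!dropped) break
  }
  # branch nodes: attachment points of kept side branches that land in the
  # interior of their host path (an end-to-end continuation or a cap bump
  # within one radius of an open end is no branch)
  bn <- NULL
  for (i in which(keep & attach >= 0L)) {
    if (!keep[attach[i] + 1L]) next
    host <- edges[[attach[i] + 1L]]
    ap <- edges[[i]]$points[nrow(edges[[i]]$points), ]
    hit <- .tube_surface_dist_cpp(matrix(ap, 1, 3), host$points, host$radius)
    arc <- c(0, cumsum(sqrt(rowSums(diff(host$points)^2))))
    apos <- arc[hit$segment]  # arc position of the attachment on the host
    dend <- min(apos, arc[length(arc)] - apos)
    if (dend > max(1.5 * max(voxel_size), hit$radius)) bn <- rbind(bn, ap)
  }
  # single-point edges (isolated voxels) are dropped unless alone
  ok_pts <- vapply(edges, function(e) nrow(e$points) >= 2L, logical(1))
  keep <- keep & (ok_pts | !any(ok_pts))
  net <- vessel_network(edges[keep], branch_nodes = bn,
                        extent = d * voxel_size)
  net$mask <- mask
  net
}

#' Segment somata from a cell-body channel
#'
#' Gaussian pre-smooth, automatic (or fixed) threshold, 3D connected-component
#' labeling, and per-detection measurement: centroid, voxel count and volume,
#' a watertight marching-tetrahedra surface mesh extracted from the smoothed
#' intensity at the threshold level, and its surface area. Detections touching
#' the volume border are flagged (their geometry may be truncated), not
#' dropped.
#'
#' @param vol a [volume()].
#' @param channel soma channel name.
#' @param method,threshold threshold rule as in [threshold_mask()].
#' @param min_voxels minimum voxel count per detection.
#' @param smooth_sigma pre-smoothing sigma in µm (single value, isotropic).
#' @return list of `pv_soma` objects (possibly empty), each with `id`,
#'   `centroid` (µm), `n_voxels`, `volume`, `surface_area`, `mesh`,
#'   `radius_equiv` and `border` flag.
#' @export
segment_somata <- function(vol, channel, method = c("otsu", "fixed"),
                           threshold = NULL, min_voxels = 30L,
                           smooth_sigma = 0.3) {
  method <- match.arg(method)
  ch <- get_channel(vol, channel)
  if (all(ch == 0)) return(list())
  v <- vol$voxel_size
  d <- dim(ch)
  sm <- ch
  if (smooth_sigma > 0)
    .gauss_blur3_cpp(sm, as.integer(d), smooth_sigma / v)
  thr <- if (method == "fixed") {
    if (is.null(threshold)) stop("method 'fixed' requires a threshold")
    threshold
  } else otsu_threshold(sm)
  mask <- sm >= thr
  lab <- .label3d_cpp(mask, as.integer(d), 26L)
  sizes <- tabulate(lab)
  keep <- which(sizes >= min_voxels)
  out <- vector("list", length(keep))
  voxvol <- prod(v)
  for (oi in seq_along(keep)) {
    li <- keep[oi]
    vox <- arrayInd(which(lab == li), d)
    centroid <- (colMeans(vox) - 0.5) * v
    border <- any(vox == 1L) || any(sweep(vox, 2, d, "=="))
    # mesh from the smoothed field restricted to this component
    lo <- pmax(apply(vox, 2, min) - 3L, 1L)
    hi <- pmin(apply(vox, 2, max) + 3L, d)
    sub <- sm[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
    sublab <- lab[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
    sub[sublab != 0L & sublab != li] <- 0
    mesh <- mesh_from_field(sub, v, thr, origin = (lo - 1L) * v)
    out[[oi]] <- structure(
      list(id = oi, centroid = centroid, n_voxels = nrow(vox),
           volume = nrow(vox) * voxvol, mesh = mesh,
           surface_area = mesh_area(mesh),
           radius_equiv = (3 * nrow(vox) * voxvol / (4 * pi))^(1 / 3),
           border = border, voxels = vox, threshold = thr),
      class = "pv_soma")
  }
  out
}

#' @export
print.pv_soma <- function(x, ...) {
  cat("<pv_soma> id ", x$id, " centroid (",
      paste(round(x$centroid, 2), collapse = ", "), ") µm, volume ",
      round(x$volume, 1), " µm³, surface ", round(x$surface_area, 1),
      " µm²", if (x$border) " [border]", "\n", sep = "")
  invisible(x)
}
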
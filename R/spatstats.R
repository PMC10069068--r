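#' Depth histogram of cell occurrence
#'
#' Counts all cells and vasculature-associated cells in 25 µm bins of
#' cortical depth, the grid-aligned census used for layer distribution
#' analysis.
#'
#' @param cells data.frame with columns `depth` (µm from the cortical
#'   surface) and logical `is_vol`; optionally `id`.
#' @param extent_depth sampled depth extent (µm).
#' @param bin bin pitch (µm), default 25.
#' @return data.frame of class `pv_depth_profile` with bin edges and per-bin
#'   total and vOL counts; bins tile `[0, ceiling(extent/bin)*bin]`.
#' @export
depth_histogram <- function(cells, extent_depth, bin = 25) {
  ids <- cells$id %||% seq_len(nrow(cells))
  bad <- which(cells$depth < 0 | cells$depth > extent_depth)
  if (length(bad))
    stop("cells outside the sampled depth: id ",
         paste(ids[bad], collapse = ", "))
  nb <- max(1L, ceiling(extent_depth / bin))
  edges <- seq(0, nb * bin, by = bin)
  bi <- pmin(findInterval(cells$depth, edges, rightmost.closed = TRUE), nb)
  bi <- pmax(bi, 1L)
  out <- data.frame(bin_lo = edges[-length(edges)], bin_hi = edges[-1],
                    n_total = tabulate(bi, nb),
                    n_vol = tabulate(bi[cells$is_vol], nb))
  class(out) <- c("pv_depth_profile", "data.frame")
  attr(out, "extent_depth") <- extent_depth
  out
}

#' Per-layer densities and vOL percentages
#'
#' Cell density (per 1e6 µm³ of actually sampled tissue) and
#' vasculature-associated percentage per cortical layer. Layer boundaries
#' are user-supplied depths; empty layers report density 0 and a missing
#' (NA) percentage, never 0%.
#'
#' @param cells data.frame with `depth` and `is_vol`.
#' @param layer_bounds strictly increasing depth boundaries (µm), including
#'   the outer limits, e.g. `c(0, 100, 300, 500)`.
#' @param section_area in-plane cross-section area (µm²) of the sampled
#'   region, used to convert counts to densities.
#' @return data.frame with layer, depth range, n, density (cells per 1e6
#'   µm³) and vol_pct.
#' @export
layer_stats <- function(cells, layer_bounds, section_area) {
  if (any(diff(layer_bounds) <= 0))
    stop("layer_bounds must be strictly increasing")
  nl <- length(layer_bounds) - 1L
  li <- findInterval(cells$depth, layer_bounds, rightmost.closed = TRUE)
  out <- do.call(rbind, lapply(seq_len(nl), function(l) {
    sel <- li == l
    n <- sum(sel)
    nv <- sum(cells$is_vol[sel])
    volume <- (layer_bounds[l + 1] - layer_bounds[l]) * section_area
    data.frame(layer = l, depth_lo = layer_bounds[l],
               depth_hi = layer_bounds[l + 1], n = n, n_vol = nv,
               sampled_volume = volume,
               density = n / volume * 1e6,
               vol_pct = if (n > 0) 100 * nv / n else NA_real_)
  }))
  out
}

#' Linear relation between soma density and myelin occupancy
#'
#' Least-squares line and Pearson R² for paired per-layer observations,
#' quantifying how well cell-body density predicts myelin occupancy.
#'
#' @param density per-layer soma density (predictor).
#' @param occupancy per-layer myelin occupancy (response).
#' @return list with slope, intercept and r_squared.
#' @export
density_occupancy_correlation <- function(density, occupancy) {
  ok <- is.finite(density) & is.finite(occupancy)
  density <- density[ok]; occupancy <- occupancy[ok]
  if (length(density) < 3L) stop("need at least 3 paired points")
  if (sd(density) == 0) stop("predictor is constant")
  fit <- lm(occupancy ~ density)
  sst <- sum((occupancy - mean(occupancy))^2)
  r2 <- if (sst == 0) 1 else 1 - sum(stats::residuals(fit)^2) / sst
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = r2)
}

#' Chance-association control by channel flipping
#'
#' Mirrors the vasculature channels along the horizontal in-plane axis (an
#' exact voxel involution), re-runs the full association pipeline on the
#' flipped volume, and returns the observed and flipped vOL fractions. A
#' real (non-chance) association shows a lower flipped fraction.
#'
#' @param vol a [volume()].
#' @param config a [pipeline_config()].
#' @param vessel_channels channels to mirror; defaults to every vasculature
#'   channel present (vessel label, wall markers, aqp4).
#' @return list with `observed`, `flipped` (fractions), and both analyses.
#' @export
flip_null <- function(vol, config = pipeline_config(),
                      vessel_channels = NULL) {
  if (is.null(vessel_channels))
    vessel_channels <- intersect(
      c(config$vessel_channel, config$marker_channels, "aqp4"),
      vol$channel_names)
  obs <- analyze_volume(vol, config)
  fvol <- flip_channels(vol, vessel_channels, axis = config$flip_axis)
  flp <- analyze_volume(fvol, config)
  list(observed = obs$vol_fraction, flipped = flp$vol_fraction,
       observed_analysis = obs, flipped_analysis = flp)
}

#' Two-or-more group comparison with a normality gate
#'
#' The decision rule used for all group comparisons: Shapiro-Wilk on each
#' group at 0.05; two normally distributed groups get a (paired or unpaired)
#' t-test, otherwise a Mann-Whitney test; more than two groups get a
#' Kruskal-Wallis test. Groups smaller than 3 cannot pass a normality gate
#' and force the non-parametric branch with a warning.
#'
#' @param samples named list of numeric vectors (>= 2 groups).
#' @param paired logical; paired t-test / Wilcoxon signed-rank for two
#'   groups of equal length.
#' @return list with `test`, `statistic`, `p_value`, `branch` and `n`.
#' @importFrom stats shapiro.test t.test wilcox.test kruskal.test
#' @export
compare_groups <- function(samples, paired = FALSE) {
  if (!is.list(samples) || length(samples) < 2L)
    stop("need at least two groups")
  n <- vapply(samples, length, integer(1))
  if (length(samples) > 2L) {
    k <- kruskal.test(samples)
    return(list(test = "Kruskal-Wallis", statistic = unname(k$statistic),
                p_value = k$p.value, branch = "nonparametric_multi", n = n))
  }
  x <- samples[[1]]; y <- samples[[2]]
  if (any(n < 3L)) {
    warning("group size < 3: normality gate refused, forcing Mann-Whitney")
    normal <- FALSE
  } else {
    sw <- function(v) {
      if (sd(v) == 0) return(FALSE)  # degenerate: not testably normal
      shapiro.test(v)$p.value > 0.05
    }
    normal <- sw(x) && sw(y)
  }
  if (normal) {
    tt <- t.test(x, y, paired = paired)
    list(test = if (paired) "paired t-test" else "unpaired t-test",
         statistic = unname(tt$statistic), p_value = tt$p.value,
         branch = "normal", n = n)
  } else {
    wt <- suppressWarnings(wilcox.test(x, y, paired = paired))
    list(test = if (paired) "Wilcoxon signed-rank" else "Mann-Whitney",
         statistic = unname(wt$statistic), p_value = wt$p.value,
         branch = "nonparametric", n = n)
  }
}
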
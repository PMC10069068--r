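#' Analysis configuration
#'
#' All tunable thresholds of the association pipeline in one place, with the
#' defaults used throughout: the 1 µm (inclusive) association criterion, the
#' 20 µm vessel search radius, 25 µm depth bins, the < 3 voxel vessel
#' despeckle, a 5 µm skeleton prune length and a 5 µm bifurcation tolerance.
#'
#' @param vessel_channel,soma_channel channel names used for segmentation.
#' @param marker_channels wall-marker channels tried for peak distances, in
#'   preference order.
#' @param association_threshold µm; peak distance at or below it = vOL.
#' @param search_radius µm; vessels farther away are ignored.
#' @param bifurcation_tolerance µm added to the soma radius.
#' @param contact_distance µm; mesh faces closer to the vessel wall count as
#'   contact.
#' @param prune_len skeleton prune length (µm).
#' @param min_component_size vessel-mask despeckle size (voxels).
#' @param min_soma_voxels minimum soma detection size (voxels).
#' @param refine_peaks sub-sample parabolic refinement of profile peaks.
#' @param measure_contact_area include per-soma contact areas (slower).
#' @param flip_axis in-plane axis mirrored by the chance-association null.
#' @param depth_bin depth histogram pitch (µm).
#' @return list of class `pv_config`.
#' @export
pipeline_config <- function(vessel_channel = "vessel",
                            soma_channel = "soma",
                            marker_channels = c("basement", "endothelial",
                                                "pericyte", "vessel"),
                            association_threshold = 1.0,
                            search_radius = 20,
                            bifurcation_tolerance = 5,
                            contact_distance = 0.1,
                            prune_len = 5,
                            min_component_size = 3L,
                            min_soma_voxels = 30L,
                            refine_peaks = TRUE,
                            measure_contact_area = FALSE,
                            flip_axis = 3L,
                            depth_bin = 25) {
  structure(list(vessel_channel = vessel_channel, soma_channel = soma_channel,
                 marker_channels = marker_channels,
                 association_threshold = association_threshold,
                 search_radius = search_radius,
                 bifurcation_tolerance = bifurcation_tolerance,
                 contact_distance = contact_distance, prune_len = prune_len,
                 min_component_size = min_component_size,
                 min_soma_voxels = min_soma_voxels,
                 refine_peaks = refine_peaks,
                 measure_contact_area = measure_contact_area,
                 flip_axis = as.integer(flip_axis), depth_bin = depth_bin),
            class = "pv_config")
}

#' Run the full association pipeline on a volume
#'
#' Segments the vasculature channel, extracts the centerline network,
#' segments the somata, and measures every soma's association with the
#' vessels. The headline result is the vOL fraction: the proportion of
#' (non-border) cell bodies whose peak-to-peak distance to the vessel wall
#' is at most the association threshold.
#'
#' @param vol a [volume()].
#' @param config a [pipeline_config()].
#' @return list of class `pv_analysis` with `network`, `somata`, `records`,
#'   `vol_fraction` and the `config` (hash recorded for provenance).
#' @export
analyze_volume <- function(vol, config = pipeline_config()) {
  mask <- threshold_mask(vol, config$vessel_channel,
                         min_component_size = config$min_component_size)
  network <- extract_network(mask, vol$voxel_size,
                             prune_len = config$prune_len)
  somata <- segment_somata(vol, config$soma_channel,
                           min_voxels = config$min_soma_voxels)
  records <- associate_somata(vol, network, somata, config)
  frac <- if (nrow(records)) mean(records$is_vol) else NA_real_
  structure(list(network = network, somata = somata, records = records,
                 vol_fraction = frac, config = config,
                 config_hash = config_hash(unclass(config))),
            class = "pv_analysis")
}

#' @export
print.pv_analysis <- function(x, ...) {
  cat("<pv_analysis> ", length(x$somata), " somata (",
      nrow(x$records), " analyzed), ", length(x$network$edges),
      " vessel edges\n", sep = "")
  if (is.finite(x$vol_fraction))
    cat("  vOL fraction: ", round(100 * x$vol_fraction, 1), "%\n", sep = "")
  invisible(x)
}
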
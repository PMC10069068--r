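#' Multi-channel 3D fluorescence volume
#'
#' Container for a multi-channel 3D image stack with physical voxel size.
#' Array axes are, in order: axis 1 = optical z (section thickness),
#' axis 2 and 3 = the two in-plane axes. By default axis 2 is the cortical
#' depth axis (increasing away from the pia) and axis 3 is the "horizontal"
#' in-plane axis used by the channel-flip null. All physical coordinates are
#' micrometres; the center of voxel `(i, j, k)` (1-based) is at
#' `(i - 0.5, j - 0.5, k - 0.5) * voxel_size`.
#'
#' @param data 3D array (single channel) or 4D array with channels along the
#'   fourth dimension; non-negative intensities.
#' @param voxel_size length-3 numeric, micrometres per voxel along each
#'   spatial axis. Anisotropy is allowed.
#' @param channel_names character vector naming the channels. Downstream
#'   operations address channels by name only.
#' @param depth_axis which spatial axis (1, 2 or 3) increases away from the
#'   cortical surface.
#' @param provenance optional list (source path, generating config hash, ...).
#' @return an object of class `pv_volume`.
#' @export
volume <- function(data, voxel_size, channel_names, depth_axis = 2L,
                   provenance = NULL) {
  if (length(dim(data)) == 3L) dim(data) <- c(dim(data), 1L)
  stopifnot(length(dim(data)) == 4L)
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0))
    stop("voxel_size must be three strictly positive values (µm)")
  if (length(channel_names) != dim(data)[4L])
    stop("channel_names length (", length(channel_names),
         ") does not match channel count (", dim(data)[4L], ")")
  if (anyDuplicated(channel_names))
    stop("channel names must be unique")
  depth_axis <- as.integer(depth_axis)
  if (!depth_axis %in% 1:3) stop("depth_axis must be 1, 2 or 3")
  structure(
    list(data = data, voxel_size = voxel_size,
         channel_names = as.character(channel_names),
         depth_axis = depth_axis, provenance = provenance),
    class = "pv_volume")
}

#' @export
print.pv_volume <- function(x, ...) {
  d <- dim(x$data)
  cat("<pv_volume> ", paste(d[1:3], collapse = " x "), " voxels, ",
      d[4], " channel(s)\n", sep = "")
  cat("  voxel size (µm): ", paste(signif(x$voxel_size, 4), collapse = " x "),
      "   extent (µm): ",
      paste(signif(d[1:3] * x$voxel_size, 4), collapse = " x "), "\n", sep = "")
  cat("  channels: ", paste(x$channel_names, collapse = ", "),
      "   depth axis: ", x$depth_axis, "\n", sep = "")
  invisible(x)
}

#' Extract one channel of a volume as a 3D array
#'
#' @param vol a [volume()].
#' @param channel channel name.
#' @return 3D numeric array.
#' @export
get_channel <- function(vol, channel) {
  stopifnot(inherits(vol, "pv_volume"))
  i <- match(channel, vol$channel_names)
  if (is.na(i)) stop("no channel named '", channel, "' (have: ",
                     paste(vol$channel_names, collapse = ", "), ")")
  arr <- vol$data[, , , i, drop = FALSE]
  dim(arr) <- dim(vol$data)[1:3]
  arr
}

#' Physical extent of a volume
#' @param vol a [volume()].
#' @return length-3 numeric, extent in micrometres per axis.
#' @export
vol_extent <- function(vol) dim(vol$data)[1:3] * vol$voxel_size

#' Mirror selected channels along an in-plane axis
#'
#' Exact voxel mirror (an involution): applying it twice restores the
#' original volume. Used by the chance-association null, which flips the
#' vasculature channels "horizontally" while leaving the cell channel in
#' place.
#'
#' @param vol a [volume()].
#' @param channels channel names to mirror.
#' @param axis spatial axis along which to flip; default is the in-plane
#'   axis 3 (orthogonal to the depth axis).
#' @return a new `pv_volume`.
#' @export
flip_channels <- function(vol, channels, axis = 3L) {
  stopifnot(inherits(vol, "pv_volume"))
  axis <- as.integer(axis)
  if (!axis %in% 1:3) stop("axis must be 1, 2 or 3")
  miss <- setdiff(channels, vol$channel_names)
  if (length(miss)) stop("unknown channel(s): ", paste(miss, collapse = ", "))
  out <- vol
  d <- dim(vol$data)
  idx <- rev(seq_len(d[axis]))
  for (ch in channels) {
    c_i <- match(ch, vol$channel_names)
    if (axis == 1L) out$data[, , , c_i] <- vol$data[idx, , , c_i]
    else if (axis == 2L) out$data[, , , c_i] <- vol$data[, idx, , c_i]
    else out$data[, , , c_i] <- vol$data[, , idx, c_i]
  }
  out
}

# depth coordinate (µm) of physical points (n x 3 matrix, axis order 1:3)
depth_of <- function(points, vol_or_axis) {
  ax <- if (inherits(vol_or_axis, "pv_volume")) vol_or_axis$depth_axis
        else as.integer(vol_or_axis)
  points[, ax]
}
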
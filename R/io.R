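#' Write a volume as multi-page TIFF with a metadata sidecar
#'
#' One TIFF page per z-plane with channels interleaved (page = (z-1) *
#' n_channels + channel), 32-bit float samples. Intensities are scaled into
#' [0, 1] by a global factor recorded — together with the voxel size, channel
#' names, depth axis and shape — in a JSON sidecar next to the TIFF, since
#' plain TIFF resolution tags cannot carry the z spacing.
#'
#' @param vol a [volume()].
#' @param path output path; ".tif" is appended when missing, and the sidecar
#'   is written to the same path with extension ".json".
#' @return invisibly, the TIFF path.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "pv_volume"))
  if (!grepl("\\.tiff?$", path)) path <- paste0(path, ".tif")
  side <- sub("\\.tiff?$", ".json", path)
  d <- dim(vol$data)
  scale <- max(vol$data, 1e-12)
  pages <- vector("list", d[1] * d[4])
  for (z in seq_len(d[1]))
    for (c_i in seq_len(d[4])) {
      pg <- vol$data[z, , , c_i] / scale
      dim(pg) <- d[2:3]
      pages[[(z - 1L) * d[4] + c_i]] <- pg
    }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  meta <- list(shape = d[1:3], n_channels = d[4],
               voxel_size = vol$voxel_size,
               channel_names = vol$channel_names,
               depth_axis = vol$depth_axis, intensity_scale = scale,
               page_order = "z_major_channel_interleaved",
               provenance = vol$provenance)
  jsonlite::write_json(meta, side, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a volume written by [write_volume()]
#'
#' Requires the JSON sidecar: voxel size is never defaulted silently — all
#' downstream distances are in µm, so a file without resolvable voxel
#' metadata is a hard error.
#'
#' @param path TIFF path.
#' @return a [volume()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  side <- sub("\\.tiff?$", ".json", path)
  if (!file.exists(side))
    stop("voxel size unresolvable: sidecar '", side, "' not found ",
         "(TIFF resolution tags cannot carry z spacing; refusing to guess)")
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  d <- as.integer(meta$shape)
  nc <- as.integer(meta$n_channels)
  if (length(pages) != d[1] * nc)
    stop("page count ", length(pages), " does not match metadata (",
         d[1] * nc, ")")
  arr <- array(0, c(d, nc))
  for (z in seq_len(d[1]))
    for (c_i in seq_len(nc)) {
      pg <- pages[[(z - 1L) * nc + c_i]]
      if (!all(dim(pg)[1:2] == d[2:3]))
        stop("corrupt page ", (z - 1L) * nc + c_i, ": dimensions ",
             paste(dim(pg), collapse = "x"))
      arr[z, , , c_i] <- pg * meta$intensity_scale
    }
  volume(arr, meta$voxel_size, meta$channel_names,
         depth_axis = meta$depth_axis,
         provenance = c(meta$provenance, list(source = path)))
}

#' Write analysis tables and a run summary
#'
#' One CSV per table (stable column order, one row per record) plus a JSON
#' summary carrying the config hash and seed, so a re-run on the same inputs
#' reproduces byte-identical outputs.
#'
#' @param tables named list of data.frames.
#' @param summary list of run-level metadata (seed, fractions, ...); the
#'   config hash is added when `config` is given.
#' @param dir output directory (created if needed).
#' @param config optional configuration list to hash into the summary.
#' @return invisibly, the paths written.
#' @export
write_report <- function(tables, summary = list(), dir, config = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (nm in names(tables)) {
    p <- file.path(dir, paste0(nm, ".csv"))
    df <- tables[[nm]]
    write.csv(df[, sort(names(df)), drop = FALSE], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  if (!is.null(config)) summary$config_hash <- config_hash(config)
  sp <- file.path(dir, "summary.json")
  jsonlite::write_json(summary, sp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(c(paths, sp))
}
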
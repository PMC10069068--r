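# Triangle meshes: list(vertices = n x 3 matrix (µm), faces = m x 3 integer)

#' Isosurface mesh of a scalar field
#'
#' Marching-tetrahedra triangulation of the `level` isosurface of a 3D field
#' sampled at voxel centers. The field is padded with a below-level frame so
#' the resulting surface is closed (watertight) even when the object touches
#' the array boundary.
#'
#' @param field 3D numeric array.
#' @param voxel_size µm per voxel per axis.
#' @param level iso level; the surface encloses `field > level`.
#' @param origin physical offset (µm) of the array corner.
#' @return mesh list with `vertices` (µm) and `faces`.
#' @export
mesh_from_field <- function(field, voxel_size, level,
                            origin = c(0, 0, 0)) {
  d <- dim(field)
  pad <- array(min(field, level) - 1, d + 2L)
  pad[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- field
  m <- .march_tets_cpp(pad, as.integer(dim(pad)), as.numeric(voxel_size),
                       as.numeric(origin) - voxel_size, level)
  m
}

#' Total surface area of a triangle mesh (µm²)
#' @param mesh mesh list from [mesh_from_field()].
#' @export
mesh_area <- function(mesh) sum(mesh_face_areas(mesh))

# per-face areas
mesh_face_areas <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

# face centroids (m x 3)
mesh_face_centroids <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  (v[f[, 1], , drop = FALSE] + v[f[, 2], , drop = FALSE] +
      v[f[, 3], , drop = FALSE]) / 3
}

#' Check that a mesh is closed (watertight)
#'
#' Every undirected edge of a closed triangle mesh is shared by exactly two
#' faces. Vertices are matched after rounding to 1e-6 µm.
#'
#' @param mesh mesh list.
#' @return logical.
#' @export
mesh_is_watertight <- function(mesh) {
  if (!nrow(mesh$faces)) return(FALSE)
  key <- apply(round(mesh$vertices, 6), 1, paste, collapse = "/")
  vid <- match(key, unique(key))
  f <- matrix(vid[mesh$faces], ncol = 3)
  # degenerate faces (zero-length edges) do not break closure accounting
  edges <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  keep <- edges[, 1] != edges[, 2]
  edges <- edges[keep, , drop = FALSE]
  ek <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  all(table(ek) %% 2 == 0)
}
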
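#' Per-vertex principal curvatures of a triangle mesh
#'
#' Estimates the second fundamental form on each face by finite differences
#' of the (area-weighted) vertex normals along the face edges — a
#' least-squares fit in a local face frame — then averages face tensors to
#' vertices with corner-angle weights and eigen-decomposes, giving the
#' principal curvatures `k1 >= k2` in 1/mm.
#'
#' Sign convention: a convex bone surface (a solid sphere of bone with
#' outward normals) has `k1, k2 > 0`. Flipping the mesh orientation negates
#' the curvatures.
#'
#' @param mesh a [triangle_mesh()] with consistent outward orientation.
#' @param check_manifold verify no edge is shared by more than two faces
#'   (default TRUE).
#' @return object of class `curvature_field`: list with `k1`, `k2`,
#'   `gaussian`, `mean` (filled by [derived_curvatures()], called
#'   internally) and `valid` (per-vertex logical, initially all TRUE).
#' @examples
#' v <- make_primitive("sphere", shape = 24, radius = 8, spacing = 0.1)
#' m <- extract_surface(v, smooth_sigma = 1)
#' cf <- principal_curvatures(m)
#' median(cf$mean)  # about 1 / (8 * 0.1 mm)
#' @export
principal_curvatures <- function(mesh, check_manifold = TRUE) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  if (nrow(mesh$faces) == 0L) stop("mesh has no faces")
  if (check_manifold) {
    st <- .mesh_edge_stats(mesh$faces, nrow(mesh$vertices))
    if (st$max_incidence > 2L)
      stop("non-manifold mesh: an edge is shared by more than two faces")
  }
  N <- vertex_normals(mesh)
  pc <- .principal_curvatures(mesh$vertices, mesh$faces, N)
  field <- structure(list(k1 = pc$k1, k2 = pc$k2, gaussian = NULL,
                          mean = NULL, valid = !is.na(pc$k1)),
                     class = "curvature_field")
  derived_curvatures(field)
}

#' Fill Gaussian and mean curvature from the principal curvatures
#'
#' Gaussian curvature `K = k1 * k2` (1/mm^2) and mean curvature
#' `H = (k1 + k2) / 2` (1/mm), exactly.
#'
#' @param field a `curvature_field` with `k1`, `k2` populated.
#' @return the field with `gaussian` and `mean` filled.
#' @export
derived_curvatures <- function(field) {
  stopifnot(inherits(field, "curvature_field"))
  field$gaussian <- field$k1 * field$k2
  field$mean <- (field$k1 + field$k2) / 2
  field
}

#' @export
print.curvature_field <- function(x, ...) {
  ok <- x$valid
  cat(sprintf(paste0("curvature_field: %d vertices (%d valid); median k1 %.3g,",
                     " k2 %.3g (1/mm)\n"),
              length(x$k1), sum(ok), median(x$k1[ok]), median(x$k2[ok])))
  invisible(x)
}

#' Restrict a curvature field's validity mask
#'
#' @param field a `curvature_field`.
#' @param valid logical vector to AND into the current mask (e.g. from
#'   [mask_cut_faces()]).
#' @return the updated field.
#' @export
restrict_valid <- function(field, valid) {
  stopifnot(inherits(field, "curvature_field"),
            length(valid) == length(field$k1))
  field$valid <- field$valid & valid
  field
}

#' Export per-vertex curvatures as CSV
#'
#' Columns: vertex index, x, y, z (mm), k1, k2 (1/mm), gaussian (1/mm^2),
#' mean (1/mm), valid.
#'
#' @param mesh a [triangle_mesh()].
#' @param field the matching `curvature_field`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_curvature_csv <- function(mesh, field, path) {
  df <- data.frame(vertex = seq_len(nrow(mesh$vertices)),
                   x = mesh$vertices[, 1], y = mesh$vertices[, 2],
                   z = mesh$vertices[, 3],
                   k1 = field$k1, k2 = field$k2,
                   gaussian = field$gaussian, mean = field$mean,
                   valid = field$valid)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' One-call curvature pipeline for a voxel volume
#'
#' Extracts the surface (with pre-smoothing, default sigma 1 voxel),
#' computes principal/Gaussian/mean curvatures and masks cut-plane vertices.
#'
#' @param volume a [voxel_volume()].
#' @param smooth_sigma pre-smoothing sigma in voxels (default 1).
#' @param iso_level iso value (default 0.5).
#' @param mask_cut exclude vertices on the volume's cut planes from the
#'   valid mask (default TRUE; the projection operator ignores the mask by
#'   default and uses every vertex).
#' @return list with `mesh` and `field`.
#' @export
curvature_pipeline <- function(volume, smooth_sigma = 1, iso_level = 0.5,
                               mask_cut = TRUE) {
  mesh <- extract_surface(volume, iso_level = iso_level,
                          smooth_sigma = smooth_sigma)
  field <- principal_curvatures(mesh, check_manifold = FALSE)
  if (mask_cut)
    field <- restrict_valid(field, mask_cut_faces(mesh, volume))
  list(mesh = mesh, field = field)
}
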
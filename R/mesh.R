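#' Triangle surface mesh
#'
#' @param vertices n x 3 numeric matrix of positions (mm).
#' @param faces m x 3 integer matrix of 1-based vertex indices, oriented
#'   with outward (away from bone) normals.
#' @return object of class `triangle_mesh` with `vertices`, `faces` and
#'   lazily computed `normals` (area-weighted unit vertex normals).
#' @export
triangle_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  if (ncol(vertices) != 3L) stop("vertices must be n x 3")
  if (nrow(faces) > 0 && (min(faces) < 1L || max(faces) > nrow(vertices)))
    stop("faces index vertices outside the mesh")
  structure(list(vertices = vertices, faces = faces, normals = NULL),
            class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("triangle_mesh: %d vertices, %d faces, area %.4g mm^2\n",
              nrow(x$vertices), nrow(x$faces), mesh_area(x)))
  invisible(x)
}

#' Per-vertex area-weighted unit normals
#' @param mesh a [triangle_mesh()].
#' @return n x 3 matrix of unit normals.
#' @export
vertex_normals <- function(mesh) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  if (!is.null(mesh$normals)) return(mesh$normals)
  .vertex_normals(mesh$vertices, mesh$faces)
}

# internal: per-face areas (mm^2)
face_areas <- function(mesh) {
  V <- mesh$vertices; F <- mesh$faces
  a <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  b <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Total mesh surface area
#'
#' @param mesh a [triangle_mesh()].
#' @param keep_faces optional logical vector (length `nrow(faces)`) of faces
#'   to include.
#' @return area in mm^2.
#' @export
mesh_area <- function(mesh, keep_faces = NULL) {
  a <- face_areas(mesh)
  if (!is.null(keep_faces)) a <- a[keep_faces]
  sum(a)
}

#' Mesh topology summary
#'
#' @param mesh a [triangle_mesh()].
#' @return list with vertex/edge/face counts, the Euler characteristic
#'   `V - E + F`, the number of boundary edges and the maximum number of
#'   faces sharing one edge (2 for a manifold mesh).
#' @export
mesh_topology <- function(mesh) {
  st <- .mesh_edge_stats(mesh$faces, nrow(mesh$vertices))
  list(n_vertices = nrow(mesh$vertices), n_edges = st$n_edges,
       n_faces = nrow(mesh$faces),
       euler_characteristic = nrow(mesh$vertices) - st$n_edges + nrow(mesh$faces),
       n_boundary_edges = st$n_boundary_edges,
       max_edge_incidence = st$max_incidence)
}

#' Extract the bone surface of a voxel volume as a triangle mesh
#'
#' Runs marching tetrahedra on the occupancy field sampled at voxel centres
#' (optionally Gaussian-smoothed first), at iso-level `iso_level`. The field
#' is padded with one layer of background so structures cut by the volume
#' boundary are capped exactly on the bounding-box faces; use
#' [mask_cut_faces()] to exclude those caps from curvature statistics. The
#' mesh is in physical mm coordinates with outward-oriented faces, cleaned
#' of degenerate triangles, and watertight whenever the structure does not
#' touch the volume boundary.
#'
#' @param volume a [voxel_volume()].
#' @param iso_level iso value on the (smoothed) 0/1 occupancy, default 0.5.
#' @param smooth_sigma Gaussian pre-smoothing sigma in voxels (default 0 =
#'   off). Smoothing (sigma of about 1 voxel) is recommended before
#'   curvature estimation: the raw binary isosurface is a faceted staircase
#'   whose curvature is concentrated in spikes.
#' @return a [triangle_mesh()].
#' @export
extract_surface <- function(volume, iso_level = 0.5, smooth_sigma = 0) {
  stopifnot(inherits(volume, "voxel_volume"))
  occ <- volume$data
  if (all(occ == 0L) || all(occ == 1L))
    stop("extraction requires both foreground and background voxels")
  field <- array(as.numeric(occ), dim(occ))
  if (smooth_sigma > 0)
    field <- array(.gaussian_smooth3d(field, dim(occ), rep(smooth_sigma, 3)),
                   dim(occ))
  d <- dim(occ)
  padded <- array(0, d + 2L)
  padded[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- field
  h <- volume$spacing
  # padded sample i (0-based) sits at origin + (i - 1 + 0.5) * h
  offset <- volume$origin - 0.5 * h
  res <- .marching_tetrahedra(as.numeric(padded), dim(padded),
                              rep(h, 3), offset, iso_level)
  if (nrow(res$vertices) == 0L) stop("no isosurface found at this iso level")
  mesh <- triangle_mesh(res$vertices, res$faces)
  mesh <- clean_mesh(mesh)
  if (smooth_sigma > 0) {
    # vertices lie (essentially) on the smoothed field's isosurface; the
    # analytic gradient of the Gaussian-convolved occupancy, evaluated
    # exactly at each vertex, gives a smooth normal field free of grid
    # interpolation artefacts
    vg <- sweep(mesh$vertices, 2, volume$origin, "-") / h - 0.5
    mesh$normals <- .field_normals_conv(as.integer(volume$data),
                                        dim(volume$data), vg, smooth_sigma)
    deg <- rowSums(mesh$normals^2) < 0.5
    if (any(deg)) mesh$normals[deg, ] <- .vertex_normals(mesh$vertices,
                                                         mesh$faces)[deg, ]
  }
  mesh
}

# drop (numerically) degenerate faces and unreferenced vertices
clean_mesh <- function(mesh, area_eps = 1e-12) {
  keep <- face_areas(mesh) > area_eps
  faces <- mesh$faces[keep, , drop = FALSE]
  used <- sort(unique(as.vector(faces)))
  remap <- integer(nrow(mesh$vertices))
  remap[used] <- seq_along(used)
  triangle_mesh(mesh$vertices[used, , drop = FALSE],
                matrix(remap[faces], ncol = 3))
}

#' Flag mesh vertices away from the volume's cut planes
#'
#' Structures clipped by the RVE box acquire artificial flat caps and sharp
#' rims on the box faces. Vertices within `tolerance` of any bounding-box
#' face are flagged invalid so they can be excluded from curvature
#' statistics and surface-area measures.
#'
#' @param mesh a [triangle_mesh()] in the volume's physical frame.
#' @param volume a [voxel_volume()] (or a 2x3 bbox matrix from
#'   [volume_bbox()]).
#' @param tolerance distance in mm; defaults to one voxel.
#' @return logical vector, `TRUE` for valid (interior) vertices.
#' @export
mask_cut_faces <- function(mesh, volume, tolerance = NULL) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  if (inherits(volume, "voxel_volume")) {
    bbox <- volume_bbox(volume)
    if (is.null(tolerance)) tolerance <- volume$spacing
  } else {
    bbox <- volume
    if (is.null(tolerance)) stop("tolerance required when passing a raw bbox")
  }
  V <- mesh$vertices
  near <- rep(FALSE, nrow(V))
  for (ax in 1:3) {
    near <- near | (V[, ax] - bbox[1, ax] <= tolerance) |
                   (bbox[2, ax] - V[, ax] <= tolerance)
  }
  !near
}

# ------------------------------------------------------------------- STL IO

#' Read a triangle mesh from an STL file
#'
#' Accepts both binary and ASCII STL. Duplicate vertices (STL stores each
#' triangle independently) are merged exactly; the number of merged
#' duplicates is recorded in attribute `"n_deduplicated"`.
#'
#' @param path STL file path.
#' @return a [triangle_mesh()].
#' @export
read_stl <- function(path) {
  size <- file.info(path)$size
  if (is.na(size) || size < 15) stop("malformed STL (byte 0): file too short")
  con <- file(path, "rb")
  on.exit(close(con))
  head_raw <- readBin(con, "raw", n = min(size, 512))
  nzb <- head_raw[head_raw != as.raw(0)]
  header_txt <- rawToChar(nzb[seq_len(min(200L, length(nzb)))])
  is_ascii <- grepl("^\\s*solid", header_txt, useBytes = TRUE) &&
    grepl("facet", header_txt, useBytes = TRUE)
  if (is_ascii) {
    tri <- read_stl_ascii(path)
  } else {
    if (size < 84) stop("malformed STL (byte 80): truncated binary header")
    seek(con, 80)
    ntri <- readBin(con, "integer", n = 1, size = 4, endian = "little")
    expected <- 84 + ntri * 50
    if (size < expected)
      stop(sprintf("malformed STL (byte %d): expected %d triangles (%d bytes), file has %d",
                   size, ntri, expected, size))
    rec <- readBin(con, "raw", n = ntri * 50)
    m <- matrix(rec, nrow = 50)
    coords <- matrix(readBin(as.raw(m[1:48, ]), "double", size = 4,
                             n = 12L * ntri, endian = "little"),
                     nrow = 12)
    tri <- t(coords[4:12, , drop = FALSE])  # drop the stored normal
  }
  # tri: ntri x 9 (v1 v2 v3 coords); deduplicate exact-equal vertices
  pts <- matrix(as.vector(t(tri)), ncol = 3, byrow = TRUE)
  key <- paste(pts[, 1], pts[, 2], pts[, 3], sep = "/")
  uid <- match(key, unique(key))
  upts <- pts[!duplicated(key), , drop = FALSE]
  faces <- matrix(uid, ncol = 3, byrow = TRUE)
  mesh <- triangle_mesh(upts, faces)
  attr(mesh, "n_deduplicated") <- nrow(pts) - nrow(upts)
  mesh
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vl) == 0L || length(vl) %% 3L != 0L)
    stop("malformed ASCII STL: vertex count not a multiple of 3")
  nums <- lapply(strsplit(trimws(vl), "\\s+"), function(x) as.numeric(x[2:4]))
  pts <- do.call(rbind, nums)
  if (anyNA(pts)) stop("malformed ASCII STL: non-numeric vertex coordinates")
  matrix(as.vector(t(pts)), ncol = 9, byrow = TRUE)
}

#' Write a triangle mesh as binary STL
#'
#' @param mesh a [triangle_mesh()].
#' @param path output path.
#' @return `path`, invisibly. Vertex coordinates are stored in single
#'   precision (the STL format's width).
#' @export
write_stl <- function(mesh, path) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  V <- mesh$vertices; F <- mesh$faces
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(80), con)
  writeBin(as.integer(nrow(F)), con, size = 4, endian = "little")
  a <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  b <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  n <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
             a[, 3] * b[, 1] - a[, 1] * b[, 3],
             a[, 1] * b[, 2] - a[, 2] * b[, 1])
  len <- sqrt(rowSums(n^2)); len[len == 0] <- 1
  n <- n / len
  zero16 <- as.raw(c(0, 0))
  for (f in seq_len(nrow(F))) {
    writeBin(c(n[f, ], V[F[f, 1], ], V[F[f, 2], ], V[F[f, 3], ]),
             con, size = 4, endian = "little")
    writeBin(zero16, con)
  }
  invisible(path)
}
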
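#' Binary voxel volume (representative volume element)
#'
#' Container for a binary 3D occupancy grid with physical voxel spacing.
#' Occupancy 1 marks the solid (bone) phase. The physical position of the
#' centre of voxel `(i, j, k)` (1-based) is
#' `origin + (c(i, j, k) - 0.5) * spacing`, so the volume occupies the box
#' `[origin, origin + dim * spacing]`.
#'
#' @param data 3D array (logical or 0/1 numeric), at least 2 voxels per axis.
#' @param spacing voxel edge length in mm (e.g. 0.035 for a 35 micron scan).
#' @param origin physical coordinate (mm) of the corner of voxel (1,1,1).
#' @return An object of class `voxel_volume` with elements `data`
#'   (integer array), `spacing` and `origin`.
#' @examples
#' v <- voxel_volume(array(1L, c(4, 4, 4)), spacing = 0.035)
#' bvtv(v)
#' @export
voxel_volume <- function(data, spacing = 0.035, origin = c(0, 0, 0)) {
  if (length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  if (any(dim(data) < 2L))
    stop("all three dimensions must be at least 2 voxels")
  if (!is.numeric(spacing) || length(spacing) != 1L || spacing <= 0)
    stop("`spacing` must be a single positive number (mm)")
  if (length(origin) != 3L || !is.numeric(origin))
    stop("`origin` must be a numeric vector of length 3")
  vals <- unique(as.vector(data))
  if (!all(vals %in% c(0, 1, TRUE, FALSE)))
    stop("occupancy must be strictly binary (0/1)")
  arr <- array(as.integer(data != 0), dim(data))
  structure(list(data = arr, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "voxel_volume")
}

#' @export
dim.voxel_volume <- function(x) dim(x$data)

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("voxel_volume: %d x %d x %d voxels, spacing %.4g mm, BV/TV %.3f\n",
              d[1], d[2], d[3], x$spacing, mean(x$data)))
  invisible(x)
}

#' Physical bounding box of a voxel volume
#'
#' @param volume a [voxel_volume()].
#' @return 2x3 matrix: first row lower corner, second row upper corner (mm).
#' @export
volume_bbox <- function(volume) {
  stopifnot(inherits(volume, "voxel_volume"))
  lo <- volume$origin
  hi <- volume$origin + dim(volume$data) * volume$spacing
  m <- rbind(lo, hi)
  dimnames(m) <- list(c("lo", "hi"), c("x", "y", "z"))
  m
}

#' Read/write a binary volume as a TIFF image stack
#'
#' The stack holds one 2D slice per z index; occupancy is stored as 0/1
#' grey values. Spacing and origin are not stored in the TIFF and must be
#' supplied on read.
#'
#' @param volume a [voxel_volume()].
#' @param path file path of the (multi-directory) TIFF.
#' @return `write_volume_tiff` returns `path` invisibly; `read_volume_tiff`
#'   returns a [voxel_volume()].
#' @export
write_volume_tiff <- function(volume, path) {
  stopifnot(inherits(volume, "voxel_volume"))
  slices <- lapply(seq_len(dim(volume$data)[3]),
                   function(k) volume$data[, , k] * 1.0)
  tiff::writeTIFF(slices, path, bits.per.sample = 8L)
  invisible(path)
}

#' @rdname write_volume_tiff
#' @param spacing,origin physical metadata to attach on read.
#' @export
read_volume_tiff <- function(path, spacing = 0.035, origin = c(0, 0, 0)) {
  slices <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(slices)) slices <- list(slices)
  arr <- array(0L, c(dim(slices[[1]])[1], dim(slices[[1]])[2], length(slices)))
  for (k in seq_along(slices)) arr[, , k] <- as.integer(slices[[k]] > 0.5)
  voxel_volume(arr, spacing = spacing, origin = origin)
}

# internal: largest connected component of a binary array (26-connectivity)
largest_component <- function(arr, connectivity = 26L) {
  lab <- .cc_label(as.integer(arr), dim(arr), as.integer(connectivity))
  sizes <- attr(lab, "sizes")
  if (length(sizes) == 0L) return(array(0L, dim(arr)))
  array(as.integer(lab == 1L), dim(arr))
}

#' Label connected components of the solid phase
#'
#' @param volume a [voxel_volume()].
#' @param connectivity 26 (default, solid phase) or 6.
#' @return integer array of component labels (0 = background), labelled in
#'   decreasing size; attribute `"sizes"` holds component voxel counts.
#' @export
connected_components <- function(volume, connectivity = 26L) {
  stopifnot(inherits(volume, "voxel_volume"))
  lab <- .cc_label(as.integer(volume$data), dim(volume$data),
                   as.integer(connectivity))
  arr <- array(as.integer(lab), dim(volume$data))
  attr(arr, "sizes") <- attr(lab, "sizes")
  arr
}
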
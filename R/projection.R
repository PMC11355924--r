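#' Number of one-voxel projection layers along an axis
#'
#' The volume is sliced along the projection direction into layers of one
#' voxel thickness: `n = ceiling(extent / spacing)`. A 6 mm cube scanned at
#' 35 microns gives n = 172; for grid-aligned volumes n equals the voxel
#' count along the axis.
#'
#' @param x a [voxel_volume()], or a physical extent in mm (then `spacing`
#'   is required).
#' @param axis projection axis (1, 2 or 3; default 3 = z).
#' @param spacing voxel size in mm when `x` is a bare extent.
#' @return integer layer count.
#' @examples
#' count_layers(6, spacing = 0.035)  # 172
#' @export
count_layers <- function(x, axis = 3L, spacing = NULL) {
  if (inherits(x, "voxel_volume")) {
    extent <- dim(x$data)[axis] * x$spacing
    spacing <- x$spacing
  } else {
    if (is.null(spacing)) stop("spacing required when passing a bare extent")
    extent <- x
  }
  as.integer(ceiling(extent / spacing - 1e-9))
}

#' Project a curvature field onto a 2D bin grid
#'
#' Every mesh vertex is assigned to the in-plane bin containing its (x, y)
#' position at the volume's voxel resolution; the bin value is the sum of
#' the curvature values of all vertices falling in the bin, across all
#' layers, divided by the layer count n. Bins receiving no vertices hold
#' exactly 0. Bin intervals are half-open `[edge, next_edge)` in physical
#' coordinates, so a vertex exactly on a bin boundary goes to the
#' higher-index bin (the top boundary, which has no higher bin, closes the
#' last bin).
#'
#' @param mesh a [triangle_mesh()].
#' @param field the matching `curvature_field`.
#' @param curvature_kind one of `"k1"`, `"k2"`, `"gaussian"`, `"mean"`.
#' @param volume the [voxel_volume()] the mesh was extracted from (defines
#'   bin edges, resolution and layer count).
#' @param axis projection axis (default 3 = z).
#' @param use_valid restrict to vertices flagged valid (default FALSE: the
#'   projection sums every vertex).
#' @return object of class `projection_image`: list with `pixels` (res_1 x
#'   res_2 matrix), `resolution`, `axis`, `curvature_kind`, `n_layers`.
#' @export
project_curvature <- function(mesh, field, curvature_kind = c("k1", "k2",
                              "gaussian", "mean"), volume, axis = 3L,
                              use_valid = FALSE) {
  curvature_kind <- match.arg(curvature_kind)
  stopifnot(inherits(mesh, "triangle_mesh"), inherits(field, "curvature_field"),
            inherits(volume, "voxel_volume"))
  vals <- field[[curvature_kind]]
  keep <- if (use_valid) field$valid else rep(TRUE, length(vals))
  keep <- keep & !is.na(vals)
  V <- mesh$vertices[keep, , drop = FALSE]
  vals <- vals[keep]
  ip <- setdiff(1:3, axis)
  bbox <- volume_bbox(volume)
  h <- volume$spacing
  res <- dim(volume$data)[ip]
  n <- count_layers(volume, axis)
  img <- matrix(0, res[1], res[2])
  if (nrow(V) > 0) {
    iidx <- floor((V[, ip[1]] - bbox[1, ip[1]]) / h)
    jidx <- floor((V[, ip[2]] - bbox[1, ip[2]]) / h)
    # top-boundary vertices close the last bin
    iidx[V[, ip[1]] >= bbox[2, ip[1]] - 1e-12 & iidx == res[1]] <- res[1] - 1
    jidx[V[, ip[2]] >= bbox[2, ip[2]] - 1e-12 & jidx == res[2]] <- res[2] - 1
    bad <- which(iidx < 0 | iidx >= res[1] | jidx < 0 | jidx >= res[2])
    if (length(bad))
      stop(sprintf("vertex %d lies outside the volume bounds", which(keep)[bad[1]]))
    acc <- tapply(vals, list(factor(iidx, levels = 0:(res[1] - 1)),
                             factor(jidx, levels = 0:(res[2] - 1))), sum)
    acc[is.na(acc)] <- 0
    img <- matrix(as.numeric(acc), res[1], res[2]) / n
  }
  structure(list(pixels = img, resolution = res, axis = axis,
                 curvature_kind = curvature_kind, n_layers = n),
            class = "projection_image")
}

#' @export
print.projection_image <- function(x, ...) {
  cat(sprintf("projection_image: %d x %d bins of %s over %d layers\n",
              x$resolution[1], x$resolution[2], x$curvature_kind, x$n_layers))
  invisible(x)
}

#' Four-channel curvature projection stack
#'
#' Stacks the k1, k2, Gaussian and mean curvature projections of one volume
#' into a single image with channels ordered (k1, k2, K, H). Each channel is
#' independently min-max rescaled to [0, 1] for CNN input; the per-channel
#' (min, max) is recorded in attribute `"channel_range"`. A constant channel
#' rescales to all zeros with a warning.
#'
#' @inheritParams project_curvature
#' @param rescale min-max rescale each channel (default TRUE).
#' @return res_1 x res_2 x 4 array with attribute `"channel_range"` (4 x 2
#'   matrix) and `"channels"`.
#' @export
projection_stack <- function(mesh, field, volume, axis = 3L, rescale = TRUE,
                             use_valid = FALSE) {
  kinds <- c("k1", "k2", "gaussian", "mean")
  imgs <- lapply(kinds, function(k)
    project_curvature(mesh, field, k, volume, axis, use_valid)$pixels)
  res <- dim(imgs[[1]])
  out <- array(0, c(res, 4L))
  ranges <- matrix(NA_real_, 4, 2, dimnames = list(kinds, c("min", "max")))
  for (i in 1:4) {
    px <- imgs[[i]]
    ranges[i, ] <- range(px)
    if (rescale) {
      rng <- ranges[i, 2] - ranges[i, 1]
      if (rng == 0) {
        warning(sprintf("channel %s is constant; rescaled to all zeros", kinds[i]))
        px <- matrix(0, res[1], res[2])
      } else {
        px <- (px - ranges[i, 1]) / rng
      }
    }
    out[, , i] <- px
  }
  attr(out, "channel_range") <- ranges
  attr(out, "channels") <- kinds
  out
}

#' Probability distribution of surface curvature values
#'
#' Normalized histogram of a curvature component over the field's valid
#' vertices (probabilities sum to 1).
#'
#' @inheritParams project_curvature
#' @param n_bins number of equal-width bins (default 50).
#' @param range numeric length-2 bin range; defaults to the data range.
#' @return object of class `curvature_histogram`: list with `bin_edges`,
#'   `mids` and `probability`.
#' @export
curvature_distribution <- function(field, curvature_kind = c("k1", "k2",
                                   "gaussian", "mean"), n_bins = 50L,
                                   range = NULL) {
  curvature_kind <- match.arg(curvature_kind)
  vals <- field[[curvature_kind]][field$valid]
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0L) stop("no valid vertices to histogram")
  if (is.null(range)) range <- base::range(vals)
  if (diff(range) == 0) range <- range + c(-0.5, 0.5)
  edges <- seq(range[1], range[2], length.out = n_bins + 1L)
  counts <- tabulate(pmin(findInterval(vals, edges, rightmost.closed = TRUE,
                                       all.inside = TRUE), n_bins), n_bins)
  structure(list(bin_edges = edges, mids = (edges[-1] + edges[-(n_bins + 1)]) / 2,
                 probability = counts / sum(counts)),
            class = "curvature_histogram")
}

#' Write a projection image (or stack channel) as 16-bit PNG plus a
#' lossless CSV float container
#'
#' @param image a `projection_image`.
#' @param path_png output PNG path (16-bit grey, min-max scaled); `NULL`
#'   to skip.
#' @param path_csv output CSV path holding the raw float pixels; `NULL` to
#'   skip.
#' @return invisible NULL.
#' @export
write_projection <- function(image, path_png = NULL, path_csv = NULL) {
  stopifnot(inherits(image, "projection_image"))
  if (!is.null(path_csv))
    write.csv(image$pixels, path_csv, row.names = FALSE)
  if (!is.null(path_png)) {
    px <- image$pixels
    rng <- range(px)
    scaled <- if (diff(rng) > 0) (px - rng[1]) / diff(rng) else px * 0
    # tiff::writeTIFF handles 16-bit; use TIFF for the image container
    tiff::writeTIFF(scaled, path_png, bits.per.sample = 16L)
  }
  invisible(NULL)
}
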
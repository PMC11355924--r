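#' Specification for the Gaussian-random-field microstructure generator
#'
#' The generator emulates trabecular-like porous cubes: a standard-normal
#' white-noise field is smoothed by an anisotropic Gaussian kernel
#' (`correlation_length` voxels, stretched per axis by `anisotropy_scales`)
#' and thresholded at the quantile that leaves `target_bvtv` of the voxels
#' solid; the largest 26-connected component is kept.
#'
#' @param shape voxels per axis (length 1 or 3).
#' @param target_bvtv target solid volume fraction, strictly in (0, 1).
#' @param correlation_length smoothing kernel sigma in voxels (>= 1);
#'   controls the trabecular feature size.
#' @param anisotropy_scales per-axis kernel stretch factors (> 0); unequal
#'   scales elongate features and raise the degree of anisotropy.
#' @param spacing voxel edge length, mm.
#' @param seed integer RNG seed; fixed seed gives bit-identical volumes.
#' @return an object of class `generator_spec`.
#' @export
generator_spec <- function(shape = 64L, target_bvtv = 0.25,
                           correlation_length = 3, anisotropy_scales = c(1, 1, 1),
                           spacing = 0.035, seed = 1L) {
  if (length(shape) == 1L) shape <- rep(shape, 3L)
  shape <- as.integer(shape)
  if (any(shape < 2L)) stop("shape must be at least 2 voxels per axis")
  if (!is.numeric(target_bvtv) || length(target_bvtv) != 1L ||
      target_bvtv <= 0 || target_bvtv >= 1)
    stop("target_bvtv must lie strictly in (0, 1)")
  if (correlation_length < 1) stop("correlation_length must be >= 1 voxel")
  if (length(anisotropy_scales) != 3L || any(anisotropy_scales <= 0))
    stop("anisotropy_scales must be three positive factors")
  if (is.null(seed)) stop("an explicit integer seed is required")
  structure(list(shape = shape, target_bvtv = target_bvtv,
                 correlation_length = correlation_length,
                 anisotropy_scales = as.numeric(anisotropy_scales),
                 spacing = spacing, seed = as.integer(seed)),
            class = "generator_spec")
}

#' Generate a trabecular-like Gaussian-random-field cube
#'
#' @param spec a [generator_spec()].
#' @return a [voxel_volume()]. The occupancy fraction before component
#'   pruning equals `target_bvtv` to the nearest voxel; after pruning only
#'   the largest 26-connected component remains, so the final BV/TV is
#'   slightly lower. If pruning loses more than 10% of the target volume
#'   (the sub-percolation regime of low fractions at large feature sizes)
#'   the threshold is recalibrated so the largest component itself reaches
#'   the target fraction.
#' @examples
#' v <- generate_grf_cube(generator_spec(shape = 24, target_bvtv = 0.3, seed = 7))
#' bvtv(v)
#' @export
generate_grf_cube <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  n <- prod(spec$shape)
  noise <- with_seed(spec$seed, rnorm(n))
  sigma <- spec$correlation_length * spec$anisotropy_scales
  field <- .gaussian_smooth3d(noise, spec$shape, sigma)
  # threshold at the quantile giving the target occupancy (type-1 quantile:
  # exact order statistic, so the count matches to the nearest voxel)
  occ_at <- function(frac) {
    thr <- quantile(field, probs = 1 - frac, type = 1, names = FALSE)
    largest_component(array(as.integer(field > thr), spec$shape))
  }
  occ <- occ_at(spec$target_bvtv)
  # below the percolation threshold (low target fractions at large feature
  # sizes) pruning to the largest component loses most of the volume; in
  # that regime the threshold is recalibrated by bisection so the largest
  # component itself carries the target fraction
  if (mean(occ) < 0.9 * spec$target_bvtv) {
    lo <- spec$target_bvtv
    hi <- min(0.99, 4 * spec$target_bvtv)
    for (it in 1:12) {
      mid <- (lo + hi) / 2
      occ_m <- occ_at(mid)
      if (mean(occ_m) < spec$target_bvtv) {
        lo <- mid
      } else {
        hi <- mid
        occ <- occ_m
      }
    }
    if (mean(occ) < 0.9 * spec$target_bvtv) occ <- occ_at(hi)
  }
  if (sum(occ) == 0L || sum(occ) == n)
    stop("degenerate generated structure: no interface surface")
  voxel_volume(occ, spacing = spec$spacing)
}

#' Voxelize an analytic primitive
#'
#' Exact voxelization by centre-of-voxel inclusion: a voxel is solid iff its
#' centre lies inside the analytic solid. Geometry parameters are expressed
#' in voxels; the returned volume carries physical `spacing` in mm.
#'
#' Kinds and their parameters (all defaulted to fit `shape` where sensible):
#' \describe{
#'   \item{solid}{fills the whole grid.}
#'   \item{sphere}{`radius`, `center` (defaults to the grid centre).}
#'   \item{cylinder}{`radius`, `axis` (1, 2 or 3), `length` (defaults to the
#'     full span, i.e. a rod crossing the cube).}
#'   \item{plate}{`thickness`, `axis` (normal direction), in-plane `extent`
#'     (defaults to the full span).}
#'   \item{torus}{`major_radius`, `minor_radius`, axis z; genus-1 solid.}
#'   \item{plate_lattice}{`n_plates` parallel plates of `thickness`
#'     separated by `gap`.}
#'   \item{rod_lattice}{`n_rods` parallel rods of `radius` on a line,
#'     centre spacing `gap`.}
#' }
#'
#' @param kind one of `"solid"`, `"sphere"`, `"cylinder"`, `"plate"`,
#'   `"torus"`, `"plate_lattice"`, `"rod_lattice"`.
#' @param shape voxels per axis (length 1 or 3).
#' @param spacing voxel edge length, mm.
#' @param ... geometry parameters, see Details.
#' @return a [voxel_volume()].
#' @examples
#' s <- make_primitive("sphere", shape = 32, radius = 10)
#' bvtv(s)
#' @export
make_primitive <- function(kind = c("solid", "sphere", "cylinder", "plate",
                                    "torus", "plate_lattice", "rod_lattice"),
                           shape = 64L, spacing = 0.035, ...) {
  kind <- match.arg(kind)
  if (length(shape) == 1L) shape <- rep(shape, 3L)
  shape <- as.integer(shape)
  p <- list(...)
  nx <- shape[1]; ny <- shape[2]; nz <- shape[3]
  # voxel centre coordinates in voxel units (centre of voxel i is i - 0.5)
  cx <- (seq_len(nx) - 0.5); cy <- (seq_len(ny) - 0.5); cz <- (seq_len(nz) - 0.5)
  X <- array(rep(cx, times = ny * nz), shape)
  Y <- array(rep(rep(cy, each = nx), times = nz), shape)
  Z <- array(rep(cz, each = nx * ny), shape)
  ctr <- shape / 2
  need_margin <- function(lo, hi, axes = 1:3) {
    # primitive must leave >= 1 background voxel on the named axes
    if (any(lo[axes] < 1) || any(hi[axes] > (shape - 1)[axes]))
      stop("primitive does not fit inside the grid with a 1-voxel margin")
  }
  occ <- switch(kind,
    solid = array(1L, shape),
    sphere = {
      r <- p$radius %||% (min(shape) / 2 - 2)
      cen <- p$center %||% ctr
      need_margin(cen - r, cen + r)
      (X - cen[1])^2 + (Y - cen[2])^2 + (Z - cen[3])^2 <= r^2
    },
    cylinder = {
      r <- p$radius %||% (min(shape) / 4)
      ax <- p$axis %||% 3L
      len <- p$length %||% shape[ax]
      ip <- setdiff(1:3, ax)
      cen <- ctr
      lo <- cen; hi <- cen
      lo[ip] <- cen[ip] - r; hi[ip] <- cen[ip] + r
      need_margin(lo, hi, axes = ip)
      axcoord <- list(X, Y, Z)[[ax]]
      ipc <- list(X, Y, Z)[ip]
      rad2 <- (ipc[[1]] - cen[ip[1]])^2 + (ipc[[2]] - cen[ip[2]])^2
      rad2 <= r^2 & abs(axcoord - cen[ax]) <= len / 2
    },
    plate = {
      th <- p$thickness %||% max(2, round(min(shape) / 8))
      ax <- p$axis %||% 3L
      ext <- p$extent %||% NULL
      cen <- ctr
      axcoord <- list(X, Y, Z)[[ax]]
      occ0 <- abs(axcoord - cen[ax]) <= th / 2
      if (!is.null(ext)) {
        ip <- setdiff(1:3, ax)
        ipc <- list(X, Y, Z)[ip]
        occ0 <- occ0 & abs(ipc[[1]] - cen[ip[1]]) <= ext / 2 &
                       abs(ipc[[2]] - cen[ip[2]]) <= ext / 2
      }
      occ0
    },
    torus = {
      R <- p$major_radius %||% (min(nx, ny) / 2 - min(nx, ny) / 6 - 2)
      r <- p$minor_radius %||% (min(nx, ny) / 8)
      need_margin(ctr - (R + r), ctr + (R + r))
      rho <- sqrt((X - ctr[1])^2 + (Y - ctr[2])^2)
      (rho - R)^2 + (Z - ctr[3])^2 <= r^2
    },
    plate_lattice = {
      np <- p$n_plates %||% 3L
      th <- p$thickness %||% max(2, round(nz / (3 * np)))
      gap <- p$gap %||% ((nz - np * th) / (np + 1))
      if (gap < 1) stop("plate lattice does not fit: increase gap or grid")
      occ0 <- array(FALSE, shape)
      for (i in seq_len(np)) {
        lo <- gap * i + th * (i - 1)
        occ0 <- occ0 | (Z >= lo & Z <= lo + th)
      }
      occ0
    },
    rod_lattice = {
      nr <- p$n_rods %||% 2L
      r <- p$radius %||% max(2, round(min(nx, ny) / (6 * nr)))
      gap <- p$gap %||% (nx / (nr + 1))
      occ0 <- array(FALSE, shape)
      for (i in seq_len(nr)) {
        cen <- c(gap * i, ny / 2)
        if (cen[1] - r < 1 || cen[1] + r > nx - 1) stop("rod lattice does not fit")
        occ0 <- occ0 | ((X - cen[1])^2 + (Y - cen[2])^2 <= r^2)
      }
      occ0
    })
  voxel_volume(array(as.integer(occ), shape), spacing = spacing)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Screen a volume against minimum-quality exclusion rules
#'
#' Mirrors the specimen-exclusion step of trabecular-cube studies: volumes
#' with very low bone volume fraction or with only minimal trabecular
#' structure (largest connected component below a size floor) are rejected.
#'
#' @param volume a [voxel_volume()].
#' @param min_bvtv minimum acceptable BV/TV (default 0.05).
#' @param min_component_size minimum voxel count of the largest 26-connected
#'   component (default 64).
#' @return list with `keep` (logical) and `reason` (`NA` when kept,
#'   otherwise `"low BV/TV"` or `"minimal trabeculae"`).
#' @export
exclusion_filter <- function(volume, min_bvtv = 0.05, min_component_size = 64L) {
  stopifnot(inherits(volume, "voxel_volume"))
  bv <- mean(volume$data)
  if (bv < min_bvtv)
    return(list(keep = FALSE, reason = "low BV/TV"))
  lab <- connected_components(volume)
  sizes <- attr(lab, "sizes")
  if (length(sizes) == 0L || max(sizes) < min_component_size)
    return(list(keep = FALSE, reason = "minimal trabeculae"))
  list(keep = TRUE, reason = NA_character_)
}
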
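#' Isotropic tissue material model
#'
#' @param youngs_modulus Young's modulus in GPa (default 15, a standard
#'   trabecular tissue value).
#' @param poisson_ratio Poisson's ratio (default 0.3).
#' @return object of class `material_model`.
#' @export
material_model <- function(youngs_modulus = 15, poisson_ratio = 0.3) {
  if (youngs_modulus <= 0) stop("Young's modulus must be positive")
  if (poisson_ratio <= -1 || poisson_ratio >= 0.5)
    stop("Poisson's ratio must lie in (-1, 0.5)")
  structure(list(youngs_modulus = youngs_modulus,
                 poisson_ratio = poisson_ratio),
            class = "material_model")
}

#' Closed-form isotropic stiffness matrix
#'
#' The 6x6 Voigt stiffness (order 11, 22, 33, 23, 13, 12, engineering
#' shears) of an isotropic solid, in GPa.
#'
#' @param material a [material_model()].
#' @return 6x6 matrix.
#' @export
isotropic_stiffness <- function(material) {
  E <- material$youngs_modulus; nu <- material$poisson_ratio
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  C <- matrix(0, 6, 6)
  C[1:3, 1:3] <- lam
  diag(C)[1:3] <- lam + 2 * mu
  diag(C)[4:6] <- mu
  C
}

#' Convert a voxel volume to a finite-element mesh description
#'
#' Each bone voxel becomes six congruent first-order tetrahedra sharing the
#' voxel's main diagonal (or one trilinear hexahedron with
#' `element = "hex"`). Floating sub-components cannot carry load under
#' kinematic uniform boundary conditions, so only the largest 26-connected
#' component is kept; the number of removed voxels is recorded.
#'
#' @param volume a [voxel_volume()].
#' @param element `"tet"` (default) or `"hex"`.
#' @return object of class `fe_mesh`: the filtered volume plus element
#'   counts (`n_elements`, `n_nodes_estimate`, `n_removed_voxels`).
#' @export
voxels_to_elements <- function(volume, element = c("tet", "hex")) {
  element <- match.arg(element)
  stopifnot(inherits(volume, "voxel_volume"))
  nvox <- sum(volume$data)
  if (nvox == 0L) stop("empty volume: no elements")
  main <- largest_component(volume$data)
  removed <- nvox - sum(main)
  if (removed > 0)
    message(sprintf("removed %d voxels in floating components", removed))
  vol2 <- voxel_volume(main, spacing = volume$spacing, origin = volume$origin)
  per <- if (element == "tet") 6L else 1L
  # node count: distinct corners of occupied voxels
  d <- dim(main)
  occ <- main == 1L
  nodes <- array(FALSE, d + 1L)
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    nodes[dx + seq_len(d[1]), dy + seq_len(d[2]), dz + seq_len(d[3])] <-
      nodes[dx + seq_len(d[1]), dy + seq_len(d[2]), dz + seq_len(d[3])] | occ
  }
  structure(list(volume = vol2, element = element,
                 n_elements = sum(main) * per,
                 n_nodes = sum(nodes),
                 n_removed_voxels = removed),
            class = "fe_mesh")
}

#' @export
print.fe_mesh <- function(x, ...) {
  cat(sprintf("fe_mesh: %d %s elements, %d nodes (%d voxels removed)\n",
              x$n_elements, x$element, x$n_nodes, x$n_removed_voxels))
  invisible(x)
}

# the six canonical unit macroscopic strain cases, Voigt order
# (e11, e22, e33, g23, g13, g12), engineering shears
canonical_strains <- function() diag(6)

#' Solve one kinematic-uniform load case
#'
#' Prescribes the affine displacement `u = eps0 x` on every node of the RVE
#' boundary faces and solves the interior by Jacobi-preconditioned
#' conjugate gradients; returns the volume-average stress over the RVE
#' (bone stress scaled by the bone fraction).
#'
#' @param mesh an [voxels_to_elements()] result (or a [voxel_volume()],
#'   converted with defaults).
#' @param material a [material_model()].
#' @param strain length-6 Voigt macroscopic strain (engineering shears).
#' @param tol relative residual tolerance (default 1e-8).
#' @param max_iter iteration cap (default 5000).
#' @return list with `avg_stress` (length-6 Voigt, GPa), `iterations`,
#'   `relres`, `n_elements`, `n_nodes`.
#' @export
solve_case <- function(mesh, material, strain, tol = 1e-8, max_iter = 5000L) {
  if (inherits(mesh, "voxel_volume")) mesh <- voxels_to_elements(mesh)
  stopifnot(inherits(mesh, "fe_mesh"), inherits(material, "material_model"))
  if (length(strain) != 6L) stop("strain must be a length-6 Voigt vector")
  if (tol <= 0) stop("tol must be positive")
  vol <- mesh$volume
  res <- .fe_solve_case(as.integer(vol$data), dim(vol$data), vol$spacing,
                        material$youngs_modulus, material$poisson_ratio,
                        as.numeric(strain), mesh$element == "hex",
                        tol, as.integer(max_iter))
  res$avg_stress <- as.numeric(res$avg_stress)
  res
}

#' Homogenized apparent stiffness tensor of a voxel structure
#'
#' Runs the six canonical kinematic-uniform load cases (three uniaxial,
#' three pure shear, unit strains) and assembles the 6x6 Voigt stiffness:
#' column j is the volume-average stress under unit strain case j. The
#' matrix is symmetrized as `(C + C') / 2` with the asymmetry norm
#' recorded.
#'
#' @param volume a [voxel_volume()] (must pass [exclusion_filter()]-style
#'   sanity: non-empty, boundary-connected).
#' @param material a [material_model()].
#' @param element `"tet"` (default) or `"hex"`.
#' @param tol PCG relative tolerance (default 1e-8).
#' @param max_iter PCG iteration cap per case.
#' @return object of class `stiffness_tensor`: list with `c` (6x6, GPa),
#'   `basis = "lab"`, `asymmetry` (max |C - C'| before symmetrization) and
#'   `solver` diagnostics.
#' @export
homogenized_stiffness <- function(volume, material = material_model(),
                                  element = c("tet", "hex"), tol = 1e-8,
                                  max_iter = 5000L) {
  element <- match.arg(element)
  mesh <- voxels_to_elements(volume, element)
  strains <- canonical_strains()
  C <- matrix(0, 6, 6)
  iters <- integer(6)
  for (j in 1:6) {
    r <- solve_case(mesh, material, strains[, j], tol, max_iter)
    C[, j] <- r$avg_stress
    iters[j] <- r$iterations
  }
  asym <- max(abs(C - t(C)))
  C <- (C + t(C)) / 2
  structure(list(c = C, basis = "lab", asymmetry = asym,
                 solver = list(iterations = iters, tol = tol,
                               element = element)),
            class = "stiffness_tensor")
}

#' @export
print.stiffness_tensor <- function(x, ...) {
  cat(sprintf("stiffness_tensor (%s frame), GPa:\n", x$basis))
  print(round(x$c, 4))
  invisible(x)
}

# Bond transformation matrix for rotating a 6x6 Voigt stiffness:
# C' = Mb C Mb' for sigma' = Mb sigma under x' = R x.
bond_matrix <- function(R) {
  i1 <- c(1, 2, 3); i2 <- list(c(2, 3), c(1, 3), c(1, 2))
  Mb <- matrix(0, 6, 6)
  Mb[1:3, 1:3] <- R[i1, i1]^2
  for (a in 1:3) for (b in 1:3)
    Mb[a, 3 + b] <- 2 * R[a, i2[[b]][1]] * R[a, i2[[b]][2]]
  for (a in 1:3) for (b in 1:3)
    Mb[3 + a, b] <- R[i2[[a]][1], b] * R[i2[[a]][2], b]
  for (a in 1:3) for (b in 1:3) {
    p <- i2[[a]]; q <- i2[[b]]
    Mb[3 + a, 3 + b] <- R[p[1], q[1]] * R[p[2], q[2]] +
                        R[p[1], q[2]] * R[p[2], q[1]]
  }
  Mb
}

#' Rotate a stiffness tensor into its fabric frame and project to
#' orthotropy
#'
#' Applies the fourth-rank rotation taking the lab axes onto the fabric
#' principal axes (e.g. the MIL ellipsoid eigenvectors from
#' [mil_ellipsoid()]), then zeroes the couplings that vanish for an
#' orthotropic solid, keeping the nine constants C11, C22, C33, C44, C55,
#' C66, C12, C13, C23. The Frobenius norm of the discarded part is
#' recorded.
#'
#' @param tensor a `stiffness_tensor`.
#' @param fabric_axes 3x3 rotation matrix, columns = fabric axes
#'   (orthonormal, right-handed).
#' @param project zero the non-orthotropic couplings (default TRUE).
#' @return a `stiffness_tensor` with `basis = "fabric"` and attribute
#'   `discarded_norm`.
#' @export
rotate_to_fabric <- function(tensor, fabric_axes, project = TRUE) {
  stopifnot(inherits(tensor, "stiffness_tensor"))
  R <- as.matrix(fabric_axes)
  if (max(abs(crossprod(R) - diag(3))) > 1e-8)
    stop("fabric_axes must be orthonormal")
  if (det(R) < 0) stop("fabric_axes must be right-handed")
  # components in the fabric frame: rotate by R' (lab -> fabric)
  Mb <- bond_matrix(t(R))
  Cf <- Mb %*% tensor$c %*% t(Mb)
  Cf <- (Cf + t(Cf)) / 2
  discarded <- 0
  if (project) {
    mask <- matrix(0, 6, 6)
    mask[1:3, 1:3] <- 1
    diag(mask) <- 1
    discarded <- sqrt(sum((Cf * (1 - mask))^2))
    Cf <- Cf * mask
  }
  out <- tensor
  out$c <- Cf
  out$basis <- "fabric"
  attr(out, "discarded_norm") <- discarded
  out
}

#' The nine orthotropic constants of a stiffness tensor
#'
#' @param tensor a `stiffness_tensor`.
#' @return named numeric vector (C11, C22, C33, C44, C55, C66, C12, C13,
#'   C23) in GPa.
#' @export
orthotropic_constants <- function(tensor) {
  C <- tensor$c
  c(C11 = C[1, 1], C22 = C[2, 2], C33 = C[3, 3],
    C44 = C[4, 4], C55 = C[5, 5], C66 = C[6, 6],
    C12 = C[1, 2], C13 = C[1, 3], C23 = C[2, 3])
}
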
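# Shared fixtures, built once per test run and cached.
.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, build(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# sphere of radius 1 mm voxelized at 25 um, with curvature field
sphere_fixture <- function() fixture("sphere", function() {
  vol <- make_primitive("sphere", shape = 96, radius = 40, spacing = 0.025)
  mesh <- extract_surface(vol, smooth_sigma = 3.5)
  field <- principal_curvatures(mesh)
  list(vol = vol, mesh = mesh, field = field, radius_mm = 1.0)
})

# cylinder of radius 0.5 mm voxelized at 25 um (spans the cube)
cylinder_fixture <- function() fixture("cylinder", function() {
  vol <- make_primitive("cylinder", shape = 64, radius = 20, spacing = 0.025)
  mesh <- extract_surface(vol, smooth_sigma = 3.5)
  field <- principal_curvatures(mesh)
  interior <- mask_cut_faces(mesh, vol, tolerance = 0.1)
  list(vol = vol, mesh = mesh, field = field, interior = interior,
       radius_mm = 0.5)
})

torus_fixture <- function() fixture("torus", function() {
  vol <- make_primitive("torus", shape = 64, major_radius = 18,
                        minor_radius = 7, spacing = 0.05)
  mesh <- extract_surface(vol, smooth_sigma = 3)
  field <- principal_curvatures(mesh)
  list(vol = vol, mesh = mesh, field = field)
})

# area-weighted (one-third of incident face areas) per-vertex areas
vertex_areas <- function(mesh) {
  fa <- trabnet:::face_areas(mesh)
  va <- numeric(nrow(mesh$vertices))
  for (j in 1:3) {
    t <- tapply(fa / 3, mesh$faces[, j], sum)
    idx <- as.integer(names(t))
    va[idx] <- va[idx] + t
  }
  va
}

# total Gaussian curvature (Gauss-Bonnet sum) over valid vertices
gauss_bonnet_sum <- function(mesh, field) {
  va <- vertex_areas(mesh)
  ok <- field$valid & !is.na(field$gaussian)
  sum(field$gaussian[ok] * va[ok])
}

# a block with `n_holes` parallel square tunnels drilled through along y
# (genus n_holes, Euler characteristic 1 - n_holes)
holey_block <- function(n_holes, spacing = 0.05) {
  arr <- array(0L, c(48, 48, 48))
  arr[8:40, 8:40, 16:32] <- 1L
  xs <- round(seq(14, 34, length.out = n_holes))
  for (x in xs) arr[(x - 2):(x + 2), , 20:28] <- 0L
  voxel_volume(arr, spacing)
}

# disjoint mixed structure: 3 plates + 2 rods
mixed_platerod_fixture <- function() fixture("mixed_platerod", function() {
  arr <- array(0L, c(64, 64, 64))
  for (zc in c(6, 28, 50)) arr[6:58, 6:58, zc:(zc + 4)] <- 1L
  xx <- matrix(rep(1:64, 64), 64)
  yy <- t(xx)
  dA <- (xx - 20)^2 + (yy - 20)^2 <= 16
  dB <- (xx - 44)^2 + (yy - 44)^2 <= 16
  for (z in 14:24) { sl <- arr[, , z]; sl[dA] <- 1L; arr[, , z] <- sl }
  for (z in 36:46) { sl <- arr[, , z]; sl[dB] <- 1L; arr[, , z] <- sl }
  voxel_volume(arr, 0.035)
})

grf_fixture <- function() fixture("grf", function() {
  generate_grf_cube(generator_spec(shape = 48, target_bvtv = 0.3,
                                   correlation_length = 3, seed = 11))
})
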
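test_that("sphere curvature matches the analytic 1/r within tolerance", {
  fx <- sphere_fixture()
  f <- fx$field
  expect_lt(abs(median(f$mean[f$valid]) - 1), 0.05)
  expect_lt(abs(median(f$k1[f$valid]) - 1), 0.05)
  expect_lt(abs(median(f$k2[f$valid]) - 1), 0.05)
})

test_that("cylinder interior has k1 = 1/r and k2 = 0", {
  fx <- cylinder_fixture()
  ok <- fx$interior & fx$field$valid
  expect_lt(abs(median(fx$field$k1[ok]) - 2) / 2, 0.05)
  expect_lt(abs(median(fx$field$k2[ok])), 0.1)
})

test_that("flat plate interior is curvature-free", {
  vol <- make_primitive("plate", shape = 48, thickness = 8, spacing = 0.035)
  mesh <- extract_surface(vol, smooth_sigma = 1)
  field <- principal_curvatures(mesh)
  ok <- mask_cut_faces(mesh, vol, tolerance = 3 * 0.035)
  expect_lt(abs(median(field$k1[ok])), 0.05)
  expect_lt(abs(median(field$k2[ok])), 0.05)
})

test_that("derived curvatures implement K = k1 k2 and H = (k1 + k2)/2", {
  f <- structure(list(k1 = c(2, 1, 1), k2 = c(0, 1, -1),
                      gaussian = NULL, mean = NULL,
                      valid = rep(TRUE, 3)), class = "curvature_field")
  f <- derived_curvatures(f)
  expect_identical(f$gaussian, c(0, 1, -1))
  expect_identical(f$mean, c(1, 1, 0))
})

test_that("k1 >= k2 everywhere and both derive exactly from the tensor", {
  fx <- sphere_fixture()
  expect_true(all(fx$field$k1 >= fx$field$k2 - 1e-12, na.rm = TRUE))
  expect_equal(fx$field$gaussian, fx$field$k1 * fx$field$k2)
  expect_equal(fx$field$mean, (fx$field$k1 + fx$field$k2) / 2)
})

test_that("Gauss-Bonnet sums give 4*pi for the sphere and 0 for the torus", {
  sp <- sphere_fixture()
  expect_lt(abs(gauss_bonnet_sum(sp$mesh, sp$field) / (4 * pi) - 1), 0.05)
  to <- torus_fixture()
  expect_lt(abs(gauss_bonnet_sum(to$mesh, to$field)), 0.5)
})

test_that("uniform scaling divides principal curvatures by the scale", {
  vol <- make_primitive("sphere", shape = 32, radius = 10, spacing = 0.1)
  mesh <- extract_surface(vol)  # face-averaged normals: scale-invariant path
  f1 <- principal_curvatures(mesh)
  scaled <- triangle_mesh(mesh$vertices * 2.5, mesh$faces)
  f2 <- principal_curvatures(scaled)
  expect_equal(f2$k1, f1$k1 / 2.5, tolerance = 1e-10)
  expect_equal(f2$k2, f1$k2 / 2.5, tolerance = 1e-10)
})

test_that("flipping mesh orientation negates the principal curvatures", {
  vol <- make_primitive("sphere", shape = 24, radius = 8, spacing = 0.1)
  mesh <- extract_surface(vol)
  f1 <- principal_curvatures(mesh)
  flipped <- triangle_mesh(mesh$vertices, mesh$faces[, c(1, 3, 2)])
  f2 <- principal_curvatures(flipped)
  expect_equal(f2$k1, -f1$k2, tolerance = 1e-10)
  expect_equal(f2$k2, -f1$k1, tolerance = 1e-10)
})

test_that("non-manifold meshes are rejected", {
  # three faces sharing one edge
  V <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(0, -1, 0))
  F <- rbind(c(1, 2, 3), c(1, 2, 4), c(1, 2, 5))
  expect_error(principal_curvatures(triangle_mesh(V, F)), "non-manifold")
})

test_that("curvature CSV export writes one row per vertex", {
  fx <- cylinder_fixture()
  path <- tempfile(fileext = ".csv")
  write_curvature_csv(fx$mesh, fx$field, path)
  df <- read.csv(path)
  expect_identical(nrow(df), nrow(fx$mesh$vertices))
  expect_true(all(c("k1", "k2", "gaussian", "mean", "valid") %in% names(df)))
  unlink(path)
})
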
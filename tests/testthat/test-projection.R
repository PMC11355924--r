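# helper: a minimal mesh/field pair with hand-placed vertices
hand_field <- function(vertices, k1) {
  n <- nrow(vertices)
  mesh <- triangle_mesh(vertices, matrix(rep(seq_len(min(n, 3)), length.out = 3),
                                         ncol = 3))
  field <- structure(list(k1 = k1, k2 = k1 * 0, gaussian = NULL, mean = NULL,
                          valid = rep(TRUE, n)), class = "curvature_field")
  list(mesh = mesh, field = derived_curvatures(field))
}

test_that("layer count follows ceil(extent / spacing)", {
  expect_identical(count_layers(6, spacing = 0.035), 172L)
  vol <- voxel_volume(array(1L, c(64, 8, 8)), spacing = 0.01)
  expect_identical(count_layers(vol, axis = 1), 64L)
  expect_identical(count_layers(1.0, spacing = 0.25), 4L)
})

test_that("a single vertex lands in its bin with value k/n", {
  vol <- voxel_volume(array(rep(c(1L, 0L), 32768), c(64, 64, 16)),
                      spacing = 0.1)
  # vertex inside bin (11, 13) (1-based): position (10.5, 12.5) * h
  hf <- hand_field(matrix(c(1.05, 1.25, 0.8), 1), k1 = 3.0)
  img <- project_curvature(hf$mesh, hf$field, "k1", vol, axis = 3)
  n <- count_layers(vol, 3)
  expect_identical(n, 16L)
  expect_equal(img$pixels[11, 13], 3.0 / n)
  expect_equal(sum(img$pixels != 0), 1L)
})

test_that("opposite curvatures in one bin cancel; empty bins are exact zeros", {
  vol <- voxel_volume(array(rep(c(1L, 0L), 2048), c(16, 16, 16)), spacing = 0.1)
  hf <- hand_field(rbind(c(0.52, 0.52, 0.5), c(0.55, 0.55, 0.9)),
                   k1 = c(2.5, -2.5))
  img <- project_curvature(hf$mesh, hf$field, "k1", vol)
  expect_true(all(img$pixels == 0))
})

test_that("boundary vertices go to the higher-index bin", {
  # spacing 0.25 keeps the bin edges exactly representable
  vol <- voxel_volume(array(rep(c(1L, 0L), 2048), c(16, 16, 16)), spacing = 0.25)
  hf <- hand_field(matrix(c(0.5, 0.5, 0.5), 1), k1 = 1.0)  # exactly on an edge
  img <- project_curvature(hf$mesh, hf$field, "k1", vol)
  expect_gt(img$pixels[3, 3], 0)  # bin [0.5, 0.75), not [0.25, 0.5)
})

test_that("vertices outside the volume raise an indexing error", {
  vol <- voxel_volume(array(rep(c(1L, 0L), 2048), c(16, 16, 16)), spacing = 0.1)
  hf <- hand_field(matrix(c(5, 0.2, 0.5), 1), k1 = 1.0)
  expect_error(project_curvature(hf$mesh, hf$field, "k1", vol), "vertex 1")
})

test_that("projection conserves the vertex curvature sum", {
  fx <- cylinder_fixture()
  img <- project_curvature(fx$mesh, fx$field, "mean", fx$vol)
  total <- sum(img$pixels) * img$n_layers
  expect_equal(total, sum(fx$field$mean), tolerance = 1e-9)
})

test_that("projection is linear in the curvature field", {
  fx <- cylinder_fixture()
  f2 <- fx$field
  f2$k1 <- 2 * fx$field$k1 + 0.7 * fx$field$mean
  a <- project_curvature(fx$mesh, f2, "k1", fx$vol)$pixels
  b <- project_curvature(fx$mesh, fx$field, "k1", fx$vol)$pixels
  d <- project_curvature(fx$mesh, fx$field, "mean", fx$vol)$pixels
  expect_equal(a, 2 * b + 0.7 * d, tolerance = 1e-12)
})

test_that("projection is invariant to vertex order", {
  fx <- cylinder_fixture()
  n <- nrow(fx$mesh$vertices)
  perm <- rev(seq_len(n))
  inv <- integer(n); inv[perm] <- seq_len(n)
  mesh2 <- triangle_mesh(fx$mesh$vertices[perm, ],
                         matrix(inv[fx$mesh$faces], ncol = 3))
  f2 <- fx$field
  for (k in c("k1", "k2", "gaussian", "mean")) f2[[k]] <- fx$field[[k]][perm]
  f2$valid <- fx$field$valid[perm]
  a <- project_curvature(mesh2, f2, "k1", fx$vol)$pixels
  b <- project_curvature(fx$mesh, fx$field, "k1", fx$vol)$pixels
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("projection stack orders channels and records min-max ranges", {
  fx <- cylinder_fixture()
  st <- projection_stack(fx$mesh, fx$field, fx$vol)
  expect_identical(dim(st), c(64L, 64L, 4L))
  expect_identical(attr(st, "channels"), c("k1", "k2", "gaussian", "mean"))
  rng <- attr(st, "channel_range")
  raw <- project_curvature(fx$mesh, fx$field, "k1", fx$vol)$pixels
  expect_equal(unname(rng["k1", ]), range(raw))
  expect_true(all(st >= 0 & st <= 1))
  # rescaling maps min -> 0 and max -> 1 per channel
  expect_equal(range(st[, , 1]), c(0, 1))
})

test_that("constant channels rescale to zero with a warning", {
  vol <- voxel_volume(array(rep(c(1L, 0L), 2048), c(16, 16, 16)), spacing = 0.1)
  hf <- hand_field(matrix(c(0.55, 0.55, 0.5), 1), k1 = 0)
  w <- capture_warnings(st <- projection_stack(hf$mesh, hf$field, vol))
  expect_identical(length(w), 4L)  # one per constant channel
  expect_true(all(grepl("constant", w)))
  expect_true(all(st == 0))
})

test_that("curvature histograms are normalized probability distributions", {
  fx <- sphere_fixture()
  h <- curvature_distribution(fx$field, "mean", n_bins = 20,
                              range = c(0.5, 1.5))
  expect_equal(sum(h$probability), 1, tolerance = 1e-9)
  expect_true(all(h$probability >= 0))
  # the mode bin contains the analytic curvature 1/r = 1 (bin width 0.05)
  mode_bin <- which.max(h$probability)
  expect_lte(h$bin_edges[mode_bin], 1 + 1e-9)
  expect_gte(h$bin_edges[mode_bin + 1], 1 - 0.05)
  # single-valued fields collapse to one bin
  f <- structure(list(k1 = rep(1, 10), k2 = rep(1, 10), gaussian = rep(1, 10),
                      mean = rep(1, 10), valid = rep(TRUE, 10)),
                 class = "curvature_field")
  h1 <- curvature_distribution(f, "k1", n_bins = 5, range = c(0, 2))
  expect_equal(max(h1$probability), 1)
})
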
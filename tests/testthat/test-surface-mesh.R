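test_that("extracted sphere surface is watertight with the analytic area", {
  fx <- sphere_fixture()
  top <- mesh_topology(fx$mesh)
  expect_identical(top$n_boundary_edges, 0L)
  expect_identical(top$max_edge_incidence, 2L)
  expect_identical(top$euler_characteristic, 2L)
  expect_lt(abs(mesh_area(fx$mesh) / (4 * pi) - 1), 0.03)
})

test_that("interior solid block extracts as a closed genus-0 surface", {
  arr <- array(0L, c(20, 20, 20))
  arr[3:18, 3:18, 3:18] <- 1L
  mesh <- extract_surface(voxel_volume(arr, 0.1))
  expect_identical(mesh_topology(mesh)$euler_characteristic, 2L)
  expect_identical(mesh_topology(mesh)$n_boundary_edges, 0L)
})

test_that("extraction fails on uniform volumes", {
  expect_error(extract_surface(make_primitive("solid", shape = 8)),
               "foreground and background")
})

test_that("structures touching the volume boundary are capped on the bbox", {
  vol <- make_primitive("cylinder", shape = 32, radius = 8, spacing = 0.1)
  mesh <- extract_surface(vol)
  # capped: still watertight, with cap vertices exactly on the z faces
  expect_identical(mesh_topology(mesh)$n_boundary_edges, 0L)
  bb <- volume_bbox(vol)
  expect_true(any(abs(mesh$vertices[, 3] - bb[1, 3]) < 1e-9))
  expect_true(any(abs(mesh$vertices[, 3] - bb[2, 3]) < 1e-9))
})

test_that("mask_cut_faces flags only vertices near the bounding box", {
  arr <- array(0L, c(20, 20, 20))
  arr[6:15, 6:15, 6:15] <- 1L
  vol <- voxel_volume(arr, 0.1)
  mesh <- extract_surface(vol)
  expect_true(all(mask_cut_faces(mesh, vol)))  # fully interior structure

  rod <- make_primitive("cylinder", shape = 32, radius = 6, spacing = 0.1)
  rmesh <- extract_surface(rod)
  valid <- mask_cut_faces(rmesh, rod)
  bb <- volume_bbox(rod)
  on_caps <- rmesh$vertices[, 3] <= bb[1, 3] + rod$spacing |
             rmesh$vertices[, 3] >= bb[2, 3] - rod$spacing
  expect_true(all(!valid[on_caps]))
  expect_true(any(valid))
  # zero tolerance flags only vertices exactly on the box
  v0 <- mask_cut_faces(rmesh, rod, tolerance = 0)
  exact <- rmesh$vertices[, 3] <= bb[1, 3] | rmesh$vertices[, 3] >= bb[2, 3]
  expect_identical(!v0, exact)
})

test_that("binary STL round trip preserves geometry and topology", {
  fx <- cylinder_fixture()
  path <- tempfile(fileext = ".stl")
  write_stl(fx$mesh, path)
  back <- read_stl(path)
  expect_identical(nrow(back$faces), nrow(fx$mesh$faces))
  # coordinates survive to single precision
  a <- fx$mesh$vertices[fx$mesh$faces[1, 1], ]
  expect_lt(min(sqrt(rowSums(sweep(back$vertices, 2, a)^2))), 1e-6)
  expect_identical(mesh_topology(back)$euler_characteristic,
                   mesh_topology(fx$mesh)$euler_characteristic)
  unlink(path)
})

test_that("ASCII STL of a unit cube parses to 12 faces, 8 vertices", {
  # hand-written ASCII STL of the unit cube
  tri <- function(a, b, c) {
    sprintf("facet normal 0 0 0\nouter loop\nvertex %s\nvertex %s\nvertex %s\nendloop\nendfacet",
            a, b, c)
  }
  v <- c("0 0 0", "1 0 0", "1 1 0", "0 1 0", "0 0 1", "1 0 1", "1 1 1", "0 1 1")
  quads <- list(c(1,2,3,4), c(5,8,7,6), c(1,5,6,2), c(2,6,7,3), c(3,7,8,4), c(4,8,5,1))
  facets <- unlist(lapply(quads, function(q)
    c(tri(v[q[1]], v[q[2]], v[q[3]]), tri(v[q[1]], v[q[3]], v[q[4]]))))
  path <- tempfile(fileext = ".stl")
  writeLines(c("solid cube", facets, "endsolid cube"), path)
  mesh <- read_stl(path)
  expect_identical(nrow(mesh$faces), 12L)
  expect_identical(nrow(mesh$vertices), 8L)
  expect_identical(attr(mesh, "n_deduplicated"), 28L)
  unlink(path)
})

test_that("truncated STL raises a parse error with a byte offset", {
  fx <- cylinder_fixture()
  path <- tempfile(fileext = ".stl")
  write_stl(fx$mesh, path)
  full <- readBin(path, "raw", n = file.info(path)$size)
  writeBin(full[1:200], path)
  expect_error(read_stl(path), "byte")
  unlink(path)
})
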
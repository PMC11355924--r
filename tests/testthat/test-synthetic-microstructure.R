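test_that("voxel_volume enforces its invariants", {
  expect_error(voxel_volume(array(1, c(1, 4, 4))), "at least 2")
  expect_error(voxel_volume(array(0.5, c(4, 4, 4))), "binary")
  expect_error(voxel_volume(array(1, c(4, 4, 4)), spacing = 0), "positive")
  v <- voxel_volume(array(1L, c(4, 4, 4)), spacing = 0.035)
  expect_equal(dim(v), c(4L, 4L, 4L))
  bb <- volume_bbox(v)
  expect_equal(unname(bb[2, ] - bb[1, ]), rep(4 * 0.035, 3))
})

test_that("generator spec validation rejects degenerate settings", {
  expect_error(generator_spec(target_bvtv = 1.2), "strictly in")
  expect_error(generator_spec(target_bvtv = 0), "strictly in")
  expect_error(generator_spec(correlation_length = 0.5), ">= 1")
  expect_error(generator_spec(anisotropy_scales = c(1, 1)), "three positive")
  expect_error(generator_spec(seed = NULL), "seed")
})

test_that("GRF cube hits the target volume fraction before pruning", {
  spec <- generator_spec(shape = 64, target_bvtv = 0.25, seed = 42)
  # reproduce the pre-pruning occupancy: quantile thresholding is exact to
  # the nearest voxel
  noise <- trabnet:::with_seed(spec$seed, rnorm(prod(spec$shape)))
  field <- trabnet:::.gaussian_smooth3d(noise, spec$shape,
                                        spec$correlation_length *
                                          spec$anisotropy_scales)
  thr <- quantile(field, probs = 0.75, type = 1, names = FALSE)
  pre <- mean(field > thr)
  expect_lte(abs(pre - 0.25), 1 / prod(spec$shape))
  # after largest-component pruning BV/TV stays close to the target
  # (pruning removes isolated islands, about 1% of the voxels here)
  vol <- generate_grf_cube(spec)
  expect_gte(bvtv(vol), 0.23)
  expect_lte(bvtv(vol), 0.26)
})

test_that("GRF cubes are bit-identical across runs for a fixed seed", {
  a <- generate_grf_cube(generator_spec(shape = 32, target_bvtv = 0.3, seed = 7))
  b <- generate_grf_cube(generator_spec(shape = 32, target_bvtv = 0.3, seed = 7))
  expect_identical(a$data, b$data)
  c2 <- generate_grf_cube(generator_spec(shape = 32, target_bvtv = 0.3, seed = 8))
  expect_false(identical(a$data, c2$data))
})

test_that("axis stretching raises the measured degree of anisotropy", {
  iso <- generate_grf_cube(generator_spec(shape = 48, target_bvtv = 0.3,
                                          correlation_length = 3, seed = 11))
  aniso <- generate_grf_cube(generator_spec(shape = 48, target_bvtv = 0.3,
                                            correlation_length = 3,
                                            anisotropy_scales = c(1, 1, 3),
                                            seed = 11))
  expect_gt(degree_of_anisotropy(aniso), degree_of_anisotropy(iso))
})

test_that("primitive voxelization matches brute-force centre inclusion", {
  vol <- make_primitive("sphere", shape = 64, radius = 20, spacing = 0.035)
  # independent triple-loop count of voxel centres inside the sphere
  count <- 0L
  ctr <- 32
  for (i in 1:64) for (j in 1:64) for (k in 1:64) {
    if ((i - 0.5 - ctr)^2 + (j - 0.5 - ctr)^2 + (k - 0.5 - ctr)^2 <= 400)
      count <- count + 1L
  }
  expect_identical(sum(vol$data), count)
})

test_that("solid primitive fills the grid; torus has genus one", {
  expect_equal(bvtv(make_primitive("solid", shape = 16)), 1.0)
  vt <- make_primitive("torus", shape = 48, major_radius = 14,
                       minor_radius = 5)
  expect_identical(euler_characteristic(vt), 0L)
})

test_that("primitives that do not fit the grid are rejected", {
  expect_error(make_primitive("sphere", shape = 32, radius = 20), "margin")
  expect_error(make_primitive("torus", shape = 32, major_radius = 14,
                              minor_radius = 4), "margin")
})

test_that("exclusion filter screens low BV/TV and fragmented volumes", {
  d <- c(16, 16, 16)
  empty <- voxel_volume(array(c(1L, rep(0L, prod(d) - 1)), d))
  r <- exclusion_filter(empty)
  expect_false(r$keep)
  expect_equal(r$reason, "low BV/TV")

  solid <- make_primitive("solid", shape = 16)
  expect_true(exclusion_filter(solid, min_bvtv = 0.05)$keep)

  # isolated single voxels: decent BV/TV but no connected structure
  arr <- array(0L, c(12, 12, 12))
  arr[seq(1, 12, 2), seq(1, 12, 2), seq(1, 12, 2)] <- 1L
  frag <- voxel_volume(arr)
  expect_gt(bvtv(frag), 0.05)
  rf <- exclusion_filter(frag)
  expect_false(rf$keep)
  expect_equal(rf$reason, "minimal trabeculae")
})

test_that("TIFF round trip preserves the occupancy grid", {
  vol <- grf_fixture()
  path <- tempfile(fileext = ".tif")
  write_volume_tiff(vol, path)
  back <- read_volume_tiff(path, spacing = vol$spacing)
  expect_identical(back$data, vol$data)
  unlink(path)
})
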
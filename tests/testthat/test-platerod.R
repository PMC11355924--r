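test_that("single plate and single rod classify cleanly", {
  plate <- make_primitive("plate", shape = 48, thickness = 8, extent = 40,
                          spacing = 0.025)
  dp <- decompose_trabeculae(plate)
  expect_identical(sum(dp$class == "plate"), 1L)
  expect_identical(sum(dp$class == "rod"), 0L)
  rod <- make_primitive("cylinder", shape = 48, radius = 6, spacing = 0.035)
  dr <- decompose_trabeculae(rod)
  expect_identical(sum(dr$class == "plate"), 0L)
  expect_identical(sum(dr$class == "rod"), 1L)
})

test_that("labels partition the solid phase exactly", {
  fx <- mixed_platerod_fixture()
  dec <- decompose_trabeculae(fx)
  expect_true(all((dec$labels > 0) == (fx$data == 1)))
  expect_identical(sort(unique(as.vector(dec$labels[dec$labels > 0]))),
                   seq_along(dec$class))
})

test_that("known plate/rod counts are recovered exactly", {
  fx <- mixed_platerod_fixture()
  dec <- decompose_trabeculae(fx)
  expect_identical(sum(dec$class == "plate"), 3L)
  expect_identical(sum(dec$class == "rod"), 2L)
  lat <- make_primitive("plate_lattice", shape = 48, n_plates = 3,
                        thickness = 6, spacing = 0.035)
  expect_identical(sum(decompose_trabeculae(lat)$class == "plate"), 3L)
  rods <- make_primitive("rod_lattice", shape = 64, n_rods = 2, radius = 5,
                         spacing = 0.035)
  expect_identical(sum(decompose_trabeculae(rods)$class == "rod"), 2L)
})

test_that("plate metrics recover slab thickness and area", {
  # full-span slab: uniform thickness, exact to one voxel
  slab <- make_primitive("plate", shape = 48, thickness = 8, spacing = 0.025)
  ms <- platerod_metrics(decompose_trabeculae(slab))
  expect_identical(ms$pn, 1L)
  expect_lte(abs(ms$pt - 0.2), 0.025 + 1e-9)      # within one voxel
  # 1 mm x 1 mm x 0.2 mm free plate at 25 um: the rounded rim thins the
  # mean thickness slightly, and the area follows volume / thickness
  plate <- make_primitive("plate", shape = 48, thickness = 8, extent = 40,
                          spacing = 0.025)
  m <- platerod_metrics(decompose_trabeculae(plate))
  expect_identical(m$pn, 1L)
  expect_lte(abs(m$pt - 0.2), 1.1 * 0.025)
  expect_lt(abs(m$pa - 1.0) / 1.0, 0.16)
})

test_that("rod metrics recover cylinder length within 10%", {
  rod <- make_primitive("cylinder", shape = c(24, 24, 64), radius = 4.3,
                        spacing = 0.035, length = 57)
  m <- platerod_metrics(decompose_trabeculae(rod))
  expect_identical(m$rn, 1L)
  expect_lt(abs(m$rl - 2.0) / 2.0, 0.10)
  # the jagged-boundary thickness bias reads the diameter thin
  expect_lt(abs(m$rd - 0.3) / 0.3, 0.35)
  expect_gt(m$rd, 0.15)
})

test_that("nearest-neighbour distance matches a two-plate fixture", {
  arr <- array(0L, c(48, 48, 48))
  arr[4:44, 4:44, 10:14] <- 1L
  arr[4:44, 4:44, 40:44] <- 1L
  dec <- decompose_trabeculae(voxel_volume(arr, 0.05))
  m <- platerod_metrics(dec)
  expect_identical(m$pn, 2L)
  expect_equal(m$nnd_pp, 1.5, tolerance = 0.01)
  expect_true(is.na(m$nnd_rr))
  expect_identical(m$rn, 0L)
  expect_true(is.na(m$rd) && is.na(m$rl))
})

test_that("metrics are stable under 90-degree rotation", {
  rod <- make_primitive("cylinder", shape = 48, radius = 6, spacing = 0.035)
  rot <- voxel_volume(aperm(rod$data, c(3, 1, 2)), spacing = rod$spacing)
  m1 <- platerod_metrics(decompose_trabeculae(rod))
  m2 <- platerod_metrics(decompose_trabeculae(rot))
  expect_identical(m1$rn, m2$rn)
  expect_equal(m1$rl, m2$rl, tolerance = 0.035)
  expect_equal(m1$rd, m2$rd, tolerance = 0.035)
})

test_that("decomposition of an empty volume errors", {
  arr <- array(0L, c(8, 8, 8))
  arr[1] <- 1L; arr[1] <- 0L  # truly empty
  expect_error(decompose_trabeculae(voxel_volume(arr)), "empty")
})
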
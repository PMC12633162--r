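# Anti-aliased multi-order rescaling.

test_that("order-0 integer upscaling replicates pixels and round-trips exactly", {
  m <- array(c(1, 3, 2, 4), c(2, 2))
  up <- vol_data(rescale_volume(m, 2, order = 0, anti_aliasing = FALSE))
  expect_identical(up, array(c(1, 1, 3, 3, 1, 1, 3, 3,
                               2, 2, 4, 4, 2, 2, 4, 4), c(4, 4)))
  x <- withr::with_seed(61, array(runif(4 * 6 * 6), c(4, 6, 6)))
  up3 <- rescale_volume(x, 2, order = 0, anti_aliasing = FALSE)
  down <- rescale_volume(up3, 0.5, order = 0, anti_aliasing = FALSE)
  expect_identical(vol_data(down), x)
})

test_that("the shape contract matches round(shape * factor) per axis", {
  x <- array(0, c(60, 64, 64))
  up <- rescale_volume(x, c(1, 2, 2), order = 1, anti_aliasing = FALSE)
  expect_identical(dim(vol_data(up)), c(60L, 128L, 128L))
  # non-integer factors use round-half-to-even
  y <- array(0, c(10, 10))
  expect_identical(dim(vol_data(rescale_volume(y, 0.25, order = 0))),
                   c(2L, 2L))
  expect_identical(dim(vol_data(rescale_volume(y, 1.17, order = 1,
                                               anti_aliasing = FALSE))),
                   c(12L, 12L))
  expect_error(rescale_volume(y, 2, order = 7), "order")
  expect_error(rescale_volume(y, -1, order = 1), "positive")
})

test_that("spline orders 2-5 match an independent reference interpolator", {
  # frozen values from an independent B-spline zoom implementation
  # (mirror boundary, pixel-centre grid mapping) on x = sin(1:11), factor 2
  x <- array(sin(1:11), c(11L, 1L))
  o2 <- c(0.859558995581, 0.859558995581, 0.948867649178, 0.795112360842,
          0.376960674722, -0.101209548758, -0.577753066651, -0.887176281702,
          -0.995067049539, -0.860446101203, -0.498587635752, -0.042116116501,
          0.456474655643, 0.814846338568, 0.991820685553, 0.922666558401,
          0.615321055893, 0.182137908931, -0.327044574901, -0.725550281005,
          -0.967900676225, -0.967900676225)
  o3 <- c(0.864709920752, 0.864709920752, 0.936622708396, 0.799269180599,
          0.392274591137, -0.112984606058, -0.574533664327, -0.891358784314,
          -0.996557487129, -0.858261489688, -0.506789589053, -0.033925891347,
          0.450112036454, 0.821014105058, 0.992846502628, 0.921308511336,
          0.622913671858, 0.174379064057, -0.319991682591, -0.732356454023,
          -0.967775092666, -0.967775092666)
  o5 <- c(0.860279130386, 0.860279130386, 0.931063079016, 0.811360495668,
          0.403345771221, -0.122281711123, -0.580881537549, -0.888845909899,
          -0.995223761935, -0.861529660318, -0.509953298377, -0.032076794618,
          0.450819104061, 0.822497375567, 0.994180749230, 0.922852694044,
          0.624910093957, 0.173655545184, -0.319864149357, -0.734171486434,
          -0.969220177647, -0.969220177647)
  for (cs in list(list(2L, o2), list(3L, o3), list(5L, o5))) {
    got <- vol_data(rescale_volume(x, c(2, 1), order = cs[[1]],
                                   anti_aliasing = FALSE))[, 1]
    expect_equal(got, cs[[2]], tolerance = 1e-9)
  }
  # order 4, 2-D downscale fixture (5x6 image filled row by row)
  x2 <- aperm(array(cos(0:29), c(6L, 5L)), c(2L, 1L))
  o4d <- array(c(0.917397548031, 0.761001769708, -0.655946994052,
                 0.016498959653, -0.216945873427, -0.778620150496), c(2L, 3L))
  got <- vol_data(rescale_volume(x2, 0.5, order = 4, anti_aliasing = FALSE))
  expect_equal(got, o4d, tolerance = 1e-9)
})

test_that("interpolation at unchanged size reproduces the samples (orders 1-5)", {
  y <- withr::with_seed(62, array(runif(24), c(12, 2)))
  for (ord in 1:5) {
    out <- vol_data(rescale_volume(y, 1, order = ord,
                                   output_shape = dim(y)))
    expect_equal(out, y, tolerance = 1e-10)
  }
})

test_that("anti-aliasing only activates for downscaling factors", {
  x <- withr::with_seed(63, array(runif(32 * 32), c(32, 32)))
  # upscale: anti_aliasing flag must not change the result
  u1 <- vol_data(rescale_volume(x, 2, order = 1, anti_aliasing = TRUE))
  u2 <- vol_data(rescale_volume(x, 2, order = 1, anti_aliasing = FALSE))
  expect_identical(u1, u2)
  # downscale: smoothing changes the result
  d1 <- vol_data(rescale_volume(x, 0.5, order = 1, anti_aliasing = TRUE))
  d2 <- vol_data(rescale_volume(x, 0.5, order = 1, anti_aliasing = FALSE))
  expect_gt(max(abs(d1 - d2)), 0)
  expect_lt(sd(d1), sd(d2))  # smoothed version has less variance
})

test_that("the benchmark harness keeps its bookkeeping contract", {
  rec <- run_benchmark(shapes = list(c(8L, 16L, 16L)), orders = c(0L, 1L),
                       repeats = 3L, warmup = 0L, seed = 5L)
  ref <- rec[rec$backend == "reference", ]
  # up/down per order
  expect_identical(nrow(ref), 4L)
  expect_true(all(ref$repeats == 3L))
  expect_true(all(vapply(strsplit(ref$wall_seconds, ";"), length, 0L) == 3L))
  # reference-only machine: no speedup reported
  expect_true(all(is.na(ref$speedup)))
})
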
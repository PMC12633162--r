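# Otsu thresholding, channel normalization and the two-stage monolayer
# pipeline.

test_that("otsu threshold separates a two-delta histogram and matches the oracle", {
  x <- array(rep(c(0.2, 0.8), each = 32), c(8, 8))
  th <- otsu_threshold(x)
  expect_gt(th, 0.2)
  expect_lt(th, 0.8)
  # 16-value toy image against exhaustive search over all 256 bins
  y <- withr::with_seed(51, array(runif(16), c(4, 4)))
  expect_equal(otsu_threshold(y), otsu_oracle(as.vector(y)))
  # and on a bimodal sample
  z <- withr::with_seed(52, array(c(rnorm(128, 0.3, 0.05),
                                    rnorm(128, 0.7, 0.05)), c(16, 16)))
  expect_equal(otsu_threshold(z), otsu_oracle(as.vector(z)))
  expect_error(otsu_threshold(array(1, c(4, 4))), "degenerate")
})

test_that("multi-otsu separates a three-delta histogram and matches the oracle", {
  x <- array(rep(c(0.1, 0.5, 0.9), c(30, 20, 14)), c(8, 8))
  th <- multi_otsu(x, 3)
  expect_length(th, 2L)
  expect_true(th[1] > 0.1 && th[1] < 0.5)
  expect_true(th[2] > 0.5 && th[2] < 0.9)
  y <- withr::with_seed(53, array(runif(64), c(8, 8)))
  expect_equal(multi_otsu(y, 3), multi_otsu_oracle(as.vector(y)))
})

test_that("channel normalization is an affine-invariant [0,1] stretch", {
  set.seed(54)
  x <- array(runif(4 * 16 * 16), c(4, 16, 16))
  n1 <- vol_data(normalize_channel(x))
  expect_gte(min(n1), 0)
  expect_lte(max(n1), 1)
  n2 <- vol_data(normalize_channel(3.7 * x + 2))
  expect_equal(n1, n2, tolerance = 1e-12)
  # already spanning [0,1] with extreme percentiles: nearly unchanged
  u <- array(seq(0, 1, length.out = 1024), c(4, 16, 16))
  expect_equal(vol_data(normalize_channel(u, probs = c(0, 1))), u,
               tolerance = 1e-6)
  expect_warning(z <- normalize_channel(array(5, c(2, 4, 4))), "constant")
  expect_true(all(vol_data(z) == 0))
})

test_that("configuration invariants are enforced", {
  expect_s3_class(monolayer_config(), "monolayer_config")
  expect_error(monolayer_config(median_ball_radius = 0), "radii")
  expect_error(monolayer_config(nuclei_downscale = 1.5), "downscale")
  expect_error(monolayer_config(membrane_otsu_classes = 1), "classes")
  expect_error(monolayer_config(cell_min_size = 0), "sizes")
})

test_that("an empty phantom yields an empty labelling, not an error", {
  empty <- array(0.1, c(8, 16, 16))
  lab <- segment_nuclei(empty + withr::with_seed(55,
    array(rnorm(prod(dim(empty)), sd = 1e-3), dim(empty))),
    monolayer_config())
  expect_true(max(lab) <= 1L)  # at most a single spurious blob from noise
  expect_error(segment_nuclei(array(0.5, c(8, 8)), monolayer_config()),
               "3-D")
})

test_that("well-separated bright spheres are each found once", {
  spec <- phantom_spec(shape = c(32L, 128L, 128L), n_objects = 5L,
                       radius_range = c(10, 12), noise_sigma = 0.02,
                       seed = 3L)
  ph <- make_nuclei_phantom(spec)
  lab <- segment_nuclei(ph$image, monolayer_config())
  expect_identical(max(lab), 5L)
  # each ground-truth centroid falls inside one distinct predicted label
  hits <- vapply(1:5, function(i) {
    cm <- round(colMeans(which(ph$labels == i, arr.ind = TRUE)))
    lab[cm[1], cm[2], cm[3]]
  }, 0L)
  expect_identical(sort(hits), 1:5)
  # labels obey the size floor and are consecutive from 1
  expect_true(all(tabulate(lab[lab > 0]) >= monolayer_config()$nuclei_min_size))
})

test_that("touching spheres are separated by the watershed step", {
  spec <- phantom_spec(shape = c(32L, 128L, 128L), n_objects = 2L,
                       radius_range = c(10, 11), noise_sigma = 0.01,
                       seed = 4L)
  ph <- make_nuclei_phantom(spec, touching = TRUE)
  lab <- segment_nuclei(ph$image, monolayer_config())
  expect_identical(max(lab), 2L)
})

test_that("the pipeline is deterministic across runs", {
  mp <- make_monolayer_phantom(phantom_spec(shape = c(32L, 128L, 128L),
                                            n_objects = 4L,
                                            radius_range = c(10, 12),
                                            noise_sigma = 0.02, seed = 56L))
  l1 <- segment_nuclei(mp$dna, monolayer_config())
  l2 <- segment_nuclei(mp$dna, monolayer_config())
  expect_identical(l1, l2)
})

test_that("cells grow from nuclear seeds and stay matched to them", {
  mp <- make_monolayer_phantom(phantom_spec(shape = c(32L, 128L, 128L),
                                            n_objects = 6L,
                                            radius_range = c(10, 12),
                                            noise_sigma = 0.02, seed = 57L))
  cfg <- monolayer_config()
  nl <- segment_nuclei(mp$dna, cfg)
  expect_identical(max(nl), 6L)
  cl <- segment_cells(mp$membrane, mp$mito, mp$dna, nl, cfg)
  expect_identical(max(cl), 6L)
  # every cell contains at least one voxel of exactly one nucleus
  for (i in seq_len(max(cl))) {
    nuc_in_cell <- unique(nl[cl == i & nl > 0L])
    expect_gte(length(nuc_in_cell), 1L)
  }
  # empty seeds -> empty cells
  expect_identical(max(segment_cells(mp$membrane, mp$mito, mp$dna,
                                     array(0L, dim(nl)), cfg)), 0L)
  expect_error(segment_cells(mp$membrane[, 1:10, ], mp$mito, mp$dna, nl, cfg),
               "shape")
})

test_that("intermediate steps are exposed and the size filter only removes", {
  mp <- make_monolayer_phantom(phantom_spec(shape = c(32L, 128L, 128L),
                                            n_objects = 4L,
                                            radius_range = c(10, 12),
                                            noise_sigma = 0.02, seed = 58L))
  lab <- segment_nuclei(mp$dna, monolayer_config(), keep_steps = TRUE)
  st <- attr(lab, "steps")
  expect_true(all(c("mask", "distance", "markers", "watershed", "upscaled")
                  %in% names(st)))
  # object count without the size filter is never smaller
  n_unfiltered <- length(unique(st$upscaled[st$upscaled > 0]))
  expect_gte(n_unfiltered, max(lab))
})

test_that("comparing a segmentation with itself is perfect", {
  mp <- make_monolayer_phantom(phantom_spec(shape = c(32L, 128L, 128L),
                                            n_objects = 3L,
                                            radius_range = c(10, 12),
                                            noise_sigma = 0.02, seed = 59L))
  rep_ <- compare_segmentations(mp$cells_gt, mp$cells_gt, mp$membrane)
  expect_true(all(rep_$ap$ap == 1))
  expect_identical(rep_$masked_psnr, Inf)
  expect_equal(rep_$masked_ssim, 1)
  # degenerate comparison: background-only prediction
  rep0 <- compare_segmentations(mp$cells_gt, array(0L, dim(mp$cells_gt)),
                                mp$membrane)
  expect_true(all(rep0$ap$ap == 0))
})
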
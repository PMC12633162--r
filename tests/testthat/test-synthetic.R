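# Seeded phantom generators.

test_that("nuclei phantoms are reproducible and respect their spec", {
  spec <- phantom_spec(shape = c(16L, 48L, 48L), n_objects = 5L,
                       radius_range = c(3, 5), seed = 71L)
  a <- make_nuclei_phantom(spec)
  b <- make_nuclei_phantom(spec)
  expect_identical(a$image, b$image)
  expect_identical(a$labels, b$labels)
  expect_identical(max(a$labels), 5L)
  # labels exactly delimit the generated objects: foreground is brighter
  expect_gt(mean(a$image[a$labels > 0]), mean(a$image[a$labels == 0]))
  # different seed -> different geometry
  c_ <- make_nuclei_phantom(phantom_spec(shape = c(16L, 48L, 48L),
                                         n_objects = 5L,
                                         radius_range = c(3, 5), seed = 72L))
  expect_false(identical(a$labels, c_$labels))
  # zero objects -> constant background + noise, empty labels
  z <- make_nuclei_phantom(phantom_spec(shape = c(8L, 16L, 16L),
                                        n_objects = 0L, noise_sigma = 0,
                                        radius_range = c(2, 3), seed = 73L))
  expect_true(all(z$labels == 0L))
  expect_equal(max(z$image), min(z$image))
})

test_that("impossible placements raise a capacity error", {
  spec <- phantom_spec(shape = c(16L, 16L, 16L), n_objects = 50L,
                       radius_range = c(4, 5), seed = 74L)
  expect_error(make_nuclei_phantom(spec), "2-voxel margin|capacity")
})

test_that("monolayer phantoms nest nuclei inside their cells", {
  mp <- make_monolayer_phantom(phantom_spec(shape = c(32L, 128L, 128L),
                                            n_objects = 6L,
                                            radius_range = c(10, 12),
                                            noise_sigma = 0.02, seed = 75L))
  expect_identical(length(unique(mp$cells_gt[mp$cells_gt > 0])), 6L)
  # every nucleus voxel lies inside the matching cell
  sel <- mp$nuclei_gt > 0L
  expect_true(all(mp$cells_gt[sel] == mp$nuclei_gt[sel]))
  # single cell occupies the whole slab
  one <- make_monolayer_phantom(phantom_spec(shape = c(16L, 48L, 48L),
                                             n_objects = 1L,
                                             radius_range = c(6, 8),
                                             noise_sigma = 0.01, seed = 76L))
  slab <- one$cells_gt[one$cells_gt > 0]
  expect_identical(unique(slab), 1L)
})

test_that("gaussian PSFs are normalized, centred and symmetric", {
  p <- make_gaussian_psf(c(9L, 13L, 13L), c(1, 2, 2))
  expect_equal(sum(p), 1, tolerance = 1e-9)
  # odd-shaped PSF equals its coordinate reversal
  expect_equal(p, p[9:1, 13:1, 13:1], tolerance = 1e-12)
  # sub-voxel sigma concentrates mass at the centre voxel
  tiny <- make_gaussian_psf(c(7L, 7L), c(0.3, 0.3))
  expect_gte(tiny[4, 4], 0.9)
})

test_that("degradation matches a direct convolution oracle when noise is off", {
  x <- withr::with_seed(77, array(runif(6 * 10 * 10), c(6, 10, 10)))
  psf <- make_gaussian_psf(c(3L, 5L, 5L), c(0.8, 1.2, 1.2))
  d1 <- vol_data(degrade(x, psf, noise = list(poisson = FALSE), seed = 1L))
  # oracle: one RL forward convolution = the blur model itself
  pad <- dim(psf) %/% 2L
  direct <- local({
    ctr <- pad
    out <- array(0, dim(x))
    ki <- as.matrix(do.call(expand.grid, lapply(dim(psf), seq_len)))
    xp <- voxkit:::pad_edge(x, pad)
    for (r in seq_len(nrow(ki))) {
      off <- ki[r, ] - 1L - ctr
      sl <- lapply(1:3, function(a)
        (pad[a] + 1L - off[a]):(pad[a] + dim(x)[a] - off[a]))
      out <- out + psf[matrix(ki[r, ], 1)] * do.call(`[`, c(list(xp), sl))
    }
    out
  })
  expect_equal(d1, direct, tolerance = 1e-6)
  # delta PSF, no noise: unchanged
  dl <- array(0, c(3, 3, 3)); dl[2, 2, 2] <- 1
  expect_equal(vol_data(degrade(x, dl, noise = list(poisson = FALSE))), x,
               tolerance = 1e-10)
  # same seed -> identical noisy outputs
  n1 <- vol_data(degrade(x, psf, seed = 9L))
  n2 <- vol_data(degrade(x, psf, seed = 9L))
  expect_identical(n1, n2)
})

test_that("band-limited fields have no power above the cutoff", {
  for (s in 1:3) {
    x <- make_band_limited(c(64L, 64L), 0.2, seed = s)
    f <- abs(fft(x))^2
    r <- sqrt(voxkit:::freq_radius_sq(dim(x)))
    expect_lt(sum(f[r > 0.2 + 1e-9]) / sum(f), 1e-10)
  }
  # cutoff 0.5 keeps the full band
  full <- make_band_limited(c(32L, 32L), 0.5, seed = 4L)
  f <- abs(fft(full))^2
  r <- sqrt(voxkit:::freq_radius_sq(dim(full)))
  expect_gt(sum(f[r > 0.4]) / sum(f), 0.01)
})
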
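# Richardson-Lucy deconvolution and automatic stopping.

test_that("a delta PSF is a fixed point of the RL iteration", {
  set.seed(31)
  x <- array(runif(6 * 8 * 8) + 0.1, c(6, 8, 8))
  psf <- array(0, c(3, 3, 3)); psf[2, 2, 2] <- 1
  out <- richardson_lucy(x, psf, 5)
  expect_equal(vol_data(out), x, tolerance = 1e-9)
})

test_that("a constant image is a flux-preserving fixed point", {
  cst <- array(2, c(8, 8))
  psf <- outer(c(0.25, 0.5, 0.25), c(0.25, 0.5, 0.25))
  out <- richardson_lucy(cst, array(psf, c(3, 3)), 10)
  expect_equal(vol_data(out), cst, tolerance = 1e-8)
})

test_that("FFT-path RL equals the direct spatial-domain oracle in 1-D/2-D/3-D", {
  # 1-D: the canonical spike case
  o1 <- array(c(0, 0, 4, 0, 0), c(5, 1))
  p1 <- array(c(0.25, 0.5, 0.25), c(3, 1))
  expect_equal(vol_data(richardson_lucy(o1, p1, 25)),
               rl_oracle(o1, p1, 25), tolerance = 1e-5)
  # 2-D random
  o2 <- withr::with_seed(32, array(runif(12 * 10) + 0.05, c(12, 10)))
  p2 <- make_gaussian_psf(c(5L, 5L), c(1, 1.3))
  expect_equal(vol_data(richardson_lucy(o2, p2, 8)),
               rl_oracle(o2, p2, 8), tolerance = 1e-5)
  # 3-D random, even-sized PSF exercises the floor(n/2) centre convention
  o3 <- withr::with_seed(33, array(runif(8 * 8 * 8) + 0.05, c(8, 8, 8)))
  p3 <- make_gaussian_psf(c(4L, 3L, 3L), c(0.8, 0.8, 0.8))
  expect_equal(vol_data(richardson_lucy(o3, p3, 6)),
               rl_oracle(o3, p3, 6), tolerance = 1e-5)
})

test_that("estimates stay non-negative and approximately conserve flux", {
  ph <- make_nuclei_phantom(phantom_spec(shape = c(16L, 32L, 32L),
                                         n_objects = 2L,
                                         radius_range = c(3, 5),
                                         background = 0.05, seed = 34L))
  psf <- make_gaussian_psf(c(5L, 7L, 7L), c(1, 1.5, 1.5))
  obs <- vol_data(degrade(ph$image, psf, noise = list(poisson = FALSE),
                          seed = 34L))
  est <- vol_data(richardson_lucy(obs, psf, 15))
  expect_true(all(est >= 0))
  expect_true(all(is.finite(est)))
  expect_lt(abs(sum(est) - sum(obs)) / sum(obs), 0.01)
})

test_that("input validation catches bad kernels and negative data", {
  x <- array(runif(16), c(4, 4))
  expect_error(richardson_lucy(x, array(0, c(3, 3)), 1), "positive sum")
  expect_error(richardson_lucy(x, array(c(-1, 2, 0, 1), c(2, 2)), 1),
               "non-negative")
  xn <- x; xn[1, 1] <- -0.5
  expect_warning(richardson_lucy(xn, make_gaussian_psf(c(3L, 3L), c(1, 1)), 1),
                 "clipped")
})

test_that("stopping rules validate their parameters", {
  expect_error(stopping_rule(tolerance = 0), "positive")
  expect_error(stopping_rule(tolerance = -1), "positive")
  expect_error(stopping_rule(patience = 0), "patience")
  r <- stopping_rule("ssim_vs_previous", 0.01, 2L)
  expect_s3_class(r, "stopping_rule")
})

test_that("a delta PSF converges right after the patience window", {
  x <- array(runif(8 * 8) + 0.2, c(8, 8))
  psf <- array(0, c(3, 3)); psf[2, 2] <- 1
  for (pat in c(1L, 3L)) {
    res <- richardson_lucy_auto(x, psf,
                                stopping_rule("psnr_vs_previous", 0.5, pat),
                                max_iterations = 20)
    expect_identical(res$stop_reason, "converged")
    # improvement is measurable from iteration 2 onward
    expect_identical(res$iterations_run, 1L + pat)
  }
})

test_that("the trace has one record per metric per completed iteration", {
  ph <- make_nuclei_phantom(phantom_spec(shape = c(12L, 16L, 16L),
                                         n_objects = 1L,
                                         radius_range = c(2, 3), seed = 36L))
  psf <- make_gaussian_psf(c(3L, 5L, 5L), c(0.8, 1, 1))
  obs <- degrade(ph$image, psf, seed = 36L)
  res <- richardson_lucy_auto(obs, psf,
                              stopping_rule("psnr_vs_previous", 0.2, 1),
                              max_iterations = 8, reference = ph$image)
  tr <- res$trace
  per_metric <- table(tr$metric)
  expect_identical(length(unique(per_metric)), 1L)
  expect_identical(as.integer(per_metric[["psnr_vs_previous"]]),
                   res$iterations_run)
  expect_true(all(c("psnr_vs_reference", "ssim_vs_reference")
                  %in% tr$metric))
  expect_lte(res$iterations_run, 8L)
})

test_that("auto-stopped deconvolution beats the blurred input on a degraded phantom", {
  psf <- make_gaussian_psf()
  ok <- 0L
  for (s in 1:3) {
    ph <- make_nuclei_phantom(phantom_spec(seed = s, poisson = TRUE))
    obs <- degrade(ph$image, psf, seed = s)
    res <- richardson_lucy_auto(obs, psf, max_iterations = 40)
    rng <- diff(range(ph$image))
    gain <- psnr(ph$image, vol_data(res$estimate), rng) -
      psnr(ph$image, vol_data(obs), rng)
    ok <- ok + (gain > 0)
  }
  expect_identical(ok, 3L)
})
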
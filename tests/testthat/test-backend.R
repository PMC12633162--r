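# Backend probing, transfers and dispatch routing.

test_that("probing never raises and always reports the reference backend", {
  expect_no_error(b <- probe_backends())
  expect_true("reference" %in% b)
  # no accelerated runtime registered here
  expect_false("accelerated" %in% probe_backends())
})

test_that("to_device degrades gracefully without an accelerated runtime", {
  x <- image_volume(array(runif(64), c(8, 8)))
  clear_dispatch_log()
  d <- to_device(x)
  expect_identical(residence(d), "reference")
  expect_identical(vol_data(d), vol_data(x))
  # idempotent and logged as a degraded transfer
  expect_identical(vol_data(to_device(d)), vol_data(x))
  ev <- vapply(dispatch_log(), function(r) r$event, "")
  expect_true("degraded" %in% ev)
})

test_that("to_host is the identity for host-resident volumes", {
  x <- image_volume(array(runif(24), c(4, 6)))
  h <- to_host(x)
  expect_identical(residence(h), "reference")
  expect_identical(vol_data(h), vol_data(x))
})

test_that("reference dispatch is bit-identical to calling the implementation", {
  x <- image_volume(array(runif(8 * 8), c(8, 8)))
  via_dispatch <- gaussian_filter(x, 1.2)
  direct <- voxkit:::.ref_gaussian(vol_data(x), 1.2, 4)
  expect_identical(vol_data(via_dispatch), direct)
  expect_identical(residence(via_dispatch), "reference")
})

test_that("unknown operations raise an error naming the namespace", {
  x <- image_volume(array(runif(16), c(4, 4)))
  expect_error(dispatch("filters.not_a_thing", x), "unsupported operation")
  expect_error(dispatch("filters.not_a_thing", x), "mirrored namespace")
})

test_that("a working accelerated backend receives dispatched calls and keeps residence", {
  register_backend("accelerated", available = function() TRUE)
  on.exit(unregister_backend("accelerated"), add = TRUE)
  register_op("filters.gaussian",
              function(x, sigma, truncate = 4)
                voxkit:::.ref_gaussian(x, sigma, truncate),
              backend = "accelerated")
  expect_setequal(probe_backends(), c("reference", "accelerated"))

  x <- image_volume(array(runif(64), c(8, 8)))
  xd <- to_device(x)
  expect_identical(residence(xd), "accelerated")
  expect_identical(vol_data(xd), vol_data(x))  # values preserved on transfer
  expect_identical(residence(to_device(xd)), "accelerated")  # idempotent

  out <- gaussian_filter(xd, 1)
  expect_identical(residence(out), "accelerated")
  # round trip conserves values and agrees with the reference path
  expect_equal(vol_data(to_host(out)), vol_data(gaussian_filter(x, 1)))
})

test_that("missing accelerated ops fall back via a logged host round-trip", {
  register_backend("accelerated", available = function() TRUE)
  on.exit(unregister_backend("accelerated"), add = TRUE)
  x <- image_volume(array(runif(6 * 6), c(6, 6)))
  xd <- to_device(x)
  clear_dispatch_log()
  out <- median_filter(xd, 1)  # not registered on the accelerated backend
  expect_identical(residence(out), "accelerated")
  ev <- vapply(dispatch_log(), function(r) r$event, "")
  expect_true("fallback" %in% ev)
  expect_identical(vol_data(to_host(out)), vol_data(median_filter(x, 1)))
})

test_that("a failing availability probe degrades to reference-only", {
  register_backend("accelerated", available = function() stop("driver error"))
  on.exit(unregister_backend("accelerated"), add = TRUE)
  expect_no_error(b <- probe_backends())
  expect_identical(b, "reference")
  x <- to_device(image_volume(array(1.0, c(2, 2))))
  expect_identical(residence(x), "reference")
})

test_that("the force-reference environment variable masks the accelerated backend", {
  register_backend("accelerated", available = function() TRUE)
  on.exit(unregister_backend("accelerated"), add = TRUE)
  withr::with_envvar(c(VOXKIT_FORCE_REFERENCE = "1"), {
    expect_identical(probe_backends(), "reference")
  })
})
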
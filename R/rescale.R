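## Multi-order anti-aliased rescaling -------------------------------------
##
## Spline interpolation of orders 0-5 with mirror boundaries. Orders >= 2 use
## the classical recursive B-spline prefilter (causal/anticausal pole
## filtering) to convert samples to spline coefficients, then evaluate the
## closed-form centred B-spline kernel at the resampled positions. Output
## coordinates map to input coordinates by the pixel-centre convention
## x_in = (i_out + 0.5) / factor - 0.5, which makes the order-0 up-2x /
## down-0.5x round trip an exact identity.

bspline_poles <- function(order) {
  switch(as.character(order),
    "2" = 2 * sqrt(2) - 3,
    "3" = sqrt(3) - 2,
    "4" = c(sqrt(664 - sqrt(438976)) + sqrt(304) - 19,
            sqrt(664 + sqrt(438976)) - sqrt(304) - 19),
    "5" = c(sqrt(67.5 - sqrt(4436.25)) + sqrt(26.25) - 6.5,
            sqrt(67.5 + sqrt(4436.25)) - sqrt(26.25) - 6.5),
    numeric(0))
}

# centred B-spline kernel of order p evaluated at t (closed form)
bspline_kernel <- function(t, p) {
  if (p == 0L) return(as.numeric(abs(t) <= 0.5))
  if (p == 1L) return(pmax(0, 1 - abs(t)))
  s <- 0
  for (k in 0:(p + 1L)) {
    s <- s + (-1)^k * choose(p + 1L, k) * pmax(t + (p + 1L) / 2 - k, 0)^p
  }
  s / factorial(p)
}

# recursive prefilter along columns of a matrix, mirror boundary, exact init
bspline_prefilter_mat <- function(m, order) {
  poles <- bspline_poles(order)
  if (!length(poles)) return(m)
  n <- nrow(m)
  if (n == 1L) return(m)
  for (z in poles) {
    m <- m * ((1 - z) * (1 - 1 / z))
    # exact causal init over the mirrored period P = 2n - 2
    P <- 2L * n - 2L
    zP <- z^P
    w <- z^(0:(n - 1L))
    w2 <- c(0, z^(P - seq_len(n - 2L)), 0)
    c0 <- drop((w + w2) %*% m) / (1 - zP)
    cp <- m
    cp[1L, ] <- c0
    for (k in 2:n) cp[k, ] <- m[k, ] + z * cp[k - 1L, ]
    cm <- cp
    cm[n, ] <- (z / (z^2 - 1)) * (cp[n, ] + z * cp[n - 1L, ])
    for (k in (n - 1L):1L) cm[k, ] <- z * (cm[k + 1L, ] - cp[k, ])
    m <- cm
  }
  m
}

# resampling weight matrix: rows = output samples, cols = input samples
resample_weights <- function(n_in, n_out, factor, order) {
  x <- (seq_len(n_out) - 0.5) / factor - 0.5  # 0-based input coordinate
  if (order == 0L) {
    j <- mirror_fold(round(x) + 1L, n_in)
    W <- matrix(0, n_out, n_in)
    W[cbind(seq_len(n_out), j)] <- 1
    return(W)
  }
  half <- (order + 1) / 2
  W <- matrix(0, n_out, n_in)
  for (i in seq_len(n_out)) {
    j0 <- ceiling(x[i] - half)
    js <- j0:(j0 + order)
    wt <- bspline_kernel(x[i] - js, order)
    jj <- mirror_fold(js + 1L, n_in)
    for (k in seq_along(js)) W[i, jj[k]] <- W[i, jj[k]] + wt[k]
  }
  W
}

#' Rescale an image by spline interpolation of order 0-5
#'
#' Mirrors the classical `rescale`/`zoom` contract: per-axis scale factors,
#' interpolation orders 0 (nearest) through 5 (quintic B-spline with recursive
#' prefiltering), mirror boundaries, and optional Gaussian anti-aliasing
#' before downscaling with per-axis sigma `sqrt(max(0, (1/f)^2 - 1)) / 2`.
#' Output shape is `round(shape * factor)` per axis (round-half-to-even).
#'
#' @param img image (array or `image_volume`).
#' @param factor positive scalar or per-axis scale factors.
#' @param order integer interpolation order in 0..5.
#' @param anti_aliasing smooth before downscaling; only ever activates on axes
#'   with factor < 1.
#' @param output_shape optional explicit output shape overriding the rounding
#'   rule (factors are then taken as `output_shape / shape` per axis).
#' @return rescaled image with the input's residence.
#' @export
rescale_volume <- function(img, factor, order = 1L, anti_aliasing = order > 0,
                           output_shape = NULL) {
  dispatch("transform.rescale", img, factor = factor, order = order,
           anti_aliasing = anti_aliasing, output_shape = output_shape)
}

.ref_rescale <- function(x, factor, order = 1L, anti_aliasing = order > 0,
                         output_shape = NULL) {
  order <- as.integer(order)
  if (order < 0L || order > 5L)
    stop("interpolation order must be in 0..5", call. = FALSE)
  d <- dim(x)
  was_logical <- is.logical(x)
  if (was_logical) x <- array(as.double(x), d)
  if (!is.null(output_shape)) {
    stopifnot(length(output_shape) == length(d))
    factor <- output_shape / d
    out_d <- as.integer(output_shape)
  } else {
    factor <- rep_len(factor, length(d))
    if (any(factor <= 0)) stop("factor must be positive", call. = FALSE)
    out_d <- as.integer(round(d * factor))
    out_d[out_d < 1L] <- 1L
  }
  factor <- out_d / d
  if (isTRUE(anti_aliasing) && any(factor < 1)) {
    sig <- sqrt(pmax(0, (1 / factor)^2 - 1)) / 2
    x <- sep_convolve(x, lapply(sig, gaussian_kernel_1d))
  }
  for (ax in seq_along(d)) {
    if (out_d[ax] == d[ax] && order <= 1L) next
    x <- apply_axis(x, ax, function(m) {
      cf <- bspline_prefilter_mat(m, order)
      resample_weights(d[ax], out_d[ax], factor[ax], order) %*% cf
    })
  }
  if (was_logical) array(x > 0.5, dim(x)) else x
}

#' Time the up-2x / down-0.5x rescaling pair across orders and backends
#'
#' For each combination of input shape, interpolation order and available
#' backend, a seeded random volume is synthesized, `warmup` untimed rounds are
#' run, and the upscale-by-2 / downscale-by-0.5 pair is timed `repeats` times
#' (anti-aliasing enabled for the downscale). Host/device transfer time is
#' excluded: arrays are placed on the backend before the stopwatch starts.
#'
#' @param shapes list of integer shape vectors.
#' @param orders integer vector of interpolation orders.
#' @param repeats timed repetitions per record.
#' @param warmup untimed warmup rounds.
#' @param seed seed for the synthesized volumes.
#' @return data.frame with one row per (shape, order, backend, operation);
#'   columns include the per-repeat wall times (seconds, `;`-separated),
#'   their median, and speedup when both backends were measured.
#' @export
run_benchmark <- function(shapes = list(c(16L, 64L, 64L)), orders = 0:5,
                          repeats = 3L, warmup = 1L, seed = 1L) {
  stopifnot(repeats >= 1L)
  backends <- probe_backends()
  rows <- list()
  for (shp in shapes) {
    x0 <- with_seed(seed, array(runif(prod(shp)), shp))
    for (ord in orders) {
      for (be in backends) {
        img <- image_volume(x0)
        if (be == "accelerated") img <- to_device(img)
        t_up <- numeric(repeats)
        t_down <- numeric(repeats)
        for (w in seq_len(warmup)) {
          up <- rescale_volume(img, 2, order = ord, anti_aliasing = FALSE)
          invisible(rescale_volume(up, 0.5, order = ord, anti_aliasing = TRUE))
        }
        for (r in seq_len(repeats)) {
          t0 <- proc.time()[["elapsed"]]
          up <- rescale_volume(img, 2, order = ord, anti_aliasing = FALSE)
          t_up[r] <- proc.time()[["elapsed"]] - t0
          t0 <- proc.time()[["elapsed"]]
          invisible(rescale_volume(up, 0.5, order = ord, anti_aliasing = TRUE))
          t_down[r] <- proc.time()[["elapsed"]] - t0
        }
        rows[[length(rows) + 1L]] <- data.frame(
          operation = c("upscale", "downscale"),
          order = ord,
          input_shape = paste(shp, collapse = "x"),
          backend = be,
          repeats = repeats,
          wall_seconds = c(paste(signif(t_up, 6), collapse = ";"),
                           paste(signif(t_down, 6), collapse = ";")),
          median_seconds = c(median(t_up), median(t_down)),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  out$speedup <- NA_real_
  if ("accelerated" %in% backends) {
    key <- paste(out$operation, out$order, out$input_shape)
    for (k in unique(key)) {
      i_ref <- which(key == k & out$backend == "reference")
      i_acc <- which(key == k & out$backend == "accelerated")
      if (length(i_ref) && length(i_acc))
        out$speedup[i_acc] <- out$median_seconds[i_ref] / out$median_seconds[i_acc]
    }
  }
  out
}
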
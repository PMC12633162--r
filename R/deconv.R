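## Richardson-Lucy deconvolution -------------------------------------------
##
## Iterative maximum-likelihood deblurring under Poisson noise:
##   e <- e * [ (o / (e (*) p)) (*) p_flipped ]
## with (*) an FFT convolution on an edge-replicated padded canvas (half the
## PSF extent per axis) to avoid circular wrap artifacts; the ratio
## denominator is stabilized by eps. The PSF is normalized to unit sum on
## entry; its centre voxel is floor(n/2) (0-based) per axis.

rl_prepare <- function(observed, psf) {
  o <- vol_data(observed)
  p <- vol_data(psf)
  if (length(dim(o)) != length(dim(p)))
    stop("PSF rank must match image rank", call. = FALSE)
  s <- sum(p)
  if (!is.finite(s) || s <= 0)
    stop("invalid kernel: PSF must have positive sum", call. = FALSE)
  if (min(p) < 0)
    stop("invalid kernel: PSF must be non-negative", call. = FALSE)
  p <- p / s
  if (min(o) < 0) {
    warning("negative observed values clipped to 0")
    o[o < 0] <- 0
  }
  pad <- dim(p) %/% 2L
  op <- pad_edge(o, pad)
  otf <- make_otf(p, dim(op))
  list(o = o, op = op, otf = otf, pad = pad, d = dim(o))
}

rl_step <- function(e, op, otf, eps) {
  conv <- fft_convolve(e, otf)
  ratio <- op / (conv + eps)
  e <- e * fft_convolve(ratio, otf, correlate = TRUE)
  e[e < 0] <- 0
  e
}

#' Richardson-Lucy deconvolution with a fixed iteration count
#'
#' @param observed non-negative image (array or `image_volume`).
#' @param psf non-negative point spread function with positive sum, same
#'   spatial rank as `observed`; normalized to unit sum internally.
#' @param n_iterations number of multiplicative updates.
#' @param eps stabilizer added to the ratio denominator.
#' @return the deconvolved estimate (non-negative, same shape and container
#'   as `observed`; initial estimate is the observed image).
#' @export
richardson_lucy <- function(observed, psf, n_iterations, eps = 1e-12) {
  stopifnot(n_iterations >= 1L)
  st <- rl_prepare(observed, psf)
  e <- st$op
  for (i in seq_len(n_iterations)) e <- rl_step(e, st$op, st$otf, eps)
  rewrap(crop_center(e, st$pad, st$d), observed)
}

#' Stopping rule for metric-guided deconvolution
#'
#' Between consecutive iterations the rule's metric is evaluated
#' (`psnr_vs_previous` / `ssim_vs_previous` compare the current estimate to
#' the previous one; `frc_resolution` tracks the single-image FRC resolution
#' of the central plane). Iteration stops once the metric's per-iteration
#' improvement stays below `tolerance` for `patience` consecutive iterations
#' — the point of diminishing returns.
#'
#' @param metric one of `"psnr_vs_previous"`, `"ssim_vs_previous"`,
#'   `"frc_resolution"`.
#' @param tolerance positive improvement threshold (dB for PSNR, SSIM units,
#'   pixels for FRC resolution).
#' @param patience number of consecutive below-tolerance iterations required.
#' @return an object of class `stopping_rule`.
#' @export
stopping_rule <- function(metric = c("psnr_vs_previous", "ssim_vs_previous",
                                     "frc_resolution"),
                          tolerance = 0.5, patience = 1L) {
  metric <- match.arg(metric)
  if (!is.numeric(tolerance) || length(tolerance) != 1L || tolerance <= 0)
    stop("tolerance must be a positive number", call. = FALSE)
  patience <- as.integer(patience)
  if (patience < 1L) stop("patience must be >= 1", call. = FALSE)
  structure(list(metric = metric, tolerance = tolerance, patience = patience),
            class = "stopping_rule")
}

rl_metric <- function(metric, prev, cur) {
  rng <- max(prev) - min(prev)
  if (rng <= 0) rng <- 1
  switch(metric,
    psnr_vs_previous = {
      p <- psnr(prev, cur, data_range = rng)
      # beyond ~140 dB the difference is numerical noise: saturate so the
      # fixed-point case registers zero improvement
      if (p > 140) Inf else p
    },
    ssim_vs_previous = {
      w <- min(7L, min(dim(prev)) - (1L - min(dim(prev)) %% 2L))
      if (w %% 2L == 0L) w <- w - 1L
      ssim(prev, cur, data_range = rng, window = max(w, 3L))
    },
    frc_resolution = {
      r <- single_image_frc(cur)$resolution
      if (is.na(r)) 0 else r
    })
}

#' Richardson-Lucy deconvolution with metric-guided automatic stopping
#'
#' Runs RL iterations, evaluating the stopping rule's metric after each one
#' (for iteration 1 the "previous" estimate is the observed image). The loop
#' stops when the absolute per-iteration change in the metric has stayed
#' below `rule$tolerance` for `rule$patience` consecutive iterations
#' (`stop_reason = "converged"`), or at `max_iterations`. Metric evaluation
#' happens on the same backend as the data.
#'
#' @inheritParams richardson_lucy
#' @param rule a [stopping_rule()].
#' @param max_iterations iteration cap.
#' @param reference optional ground-truth image; when supplied, PSNR and SSIM
#'   against it are additionally recorded in the trace (not used for
#'   stopping).
#' @return an object of class `rl_deconvolution`: fields `estimate`,
#'   `iterations_run`, `trace` (data.frame iteration/metric/value) and
#'   `stop_reason`.
#' @export
richardson_lucy_auto <- function(observed, psf, rule = stopping_rule(),
                                 max_iterations = 50L, reference = NULL,
                                 eps = 1e-12) {
  stopifnot(inherits(rule, "stopping_rule"), max_iterations >= 1L)
  max_iterations <- as.integer(max_iterations)
  st <- rl_prepare(observed, psf)
  e <- st$op
  prev_crop <- crop_center(e, st$pad, st$d)
  trace <- list()
  m_prev <- NULL
  low_run <- 0L
  stop_reason <- "max_iterations"
  iterations_run <- max_iterations
  for (i in seq_len(max_iterations)) {
    e <- rl_step(e, st$op, st$otf, eps)
    cur_crop <- crop_center(e, st$pad, st$d)
    m <- rl_metric(rule$metric, prev_crop, cur_crop)
    trace[[length(trace) + 1L]] <-
      data.frame(iteration = i, metric = rule$metric, value = m)
    if (!is.null(reference)) {
      rr <- vol_data(reference)
      rng <- max(rr) - min(rr)
      if (rng <= 0) rng <- 1
      trace[[length(trace) + 1L]] <- data.frame(
        iteration = i, metric = "psnr_vs_reference",
        value = psnr(rr, cur_crop, data_range = rng))
      trace[[length(trace) + 1L]] <- data.frame(
        iteration = i, metric = "ssim_vs_reference",
        value = ssim(rr, cur_crop, data_range = rng))
    }
    if (!is.null(m_prev)) {
      imp <- abs(m - m_prev)
      if (is.nan(imp)) imp <- 0  # e.g. Inf - Inf when nothing changes
      if (imp < rule$tolerance) low_run <- low_run + 1L else low_run <- 0L
      if (low_run >= rule$patience) {
        stop_reason <- "converged"
        iterations_run <- i
        break
      }
    }
    m_prev <- m
    prev_crop <- cur_crop
  }
  structure(list(
    estimate = rewrap(crop_center(e, st$pad, st$d), observed),
    iterations_run = iterations_run,
    trace = do.call(rbind, trace),
    stop_reason = stop_reason,
    rule = rule
  ), class = "rl_deconvolution")
}

#' @export
print.rl_deconvolution <- function(x, ...) {
  cat(sprintf("<rl_deconvolution> %d iterations (%s), metric %s\n",
              x$iterations_run, x$stop_reason, x$rule$metric))
  last <- x$trace[x$trace$metric == x$rule$metric, ]
  if (nrow(last))
    cat(sprintf("  final %s = %.4g\n", x$rule$metric,
                last$value[nrow(last)]))
  invisible(x)
}

#' @export
summary.rl_deconvolution <- function(object, ...) {
  s <- split(object$trace$value, object$trace$metric)
  out <- data.frame(metric = names(s),
                    first = vapply(s, function(v) v[1L], 0),
                    last = vapply(s, function(v) v[length(v)], 0))
  rownames(out) <- NULL
  cat(sprintf("Richardson-Lucy: %d iterations, stopped by %s\n",
              object$iterations_run, object$stop_reason))
  out
}

#' @export
plot.rl_deconvolution <- function(x, metric = NULL, ...) {
  tr <- x$trace
  if (is.null(metric)) metric <- x$rule$metric
  tr <- tr[tr$metric == metric & is.finite(tr$value), ]
  plot(tr$iteration, tr$value, type = "b", xlab = "iteration", ylab = metric,
       ...)
  invisible(x)
}
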
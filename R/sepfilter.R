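## Separable filtering machinery, padding, structuring elements, FFT helpers.

# Apply a matrix-valued transform along one axis of an n-D array.
# `fn` receives a (len_axis x n_other) matrix and must return a matrix with
# the same number of columns; rows may change (e.g. resampling).
apply_axis <- function(a, axis, fn) {
  d <- dim(a)
  nd <- length(d)
  if (nd == 1L || is.null(d)) return(fn(matrix(a, ncol = 1L))[, 1L])
  perm <- c(axis, seq_len(nd)[-axis])
  m <- matrix(aperm(a, perm), nrow = d[axis])
  r <- fn(m)
  newd <- d
  newd[axis] <- nrow(r)
  aperm(array(r, c(nrow(r), d[-axis])), order(perm))
}

# mirror-fold indices into 1..n (reflect about edge samples, period 2n-2)
mirror_fold <- function(idx, n) {
  if (n == 1L) return(rep(1L, length(idx)))
  p <- 2L * n - 2L
  j <- (idx - 1L) %% p
  j <- ifelse(j < 0L, j + p, j)
  ifelse(j >= n, p - j, j) + 1L
}

# Convolve along each axis with a symmetric kernel, mirror boundaries.
sep_convolve <- function(a, kernels) {
  d <- dim(a)
  for (ax in seq_along(d)) {
    k <- kernels[[ax]]
    if (length(k) <= 1L) next
    r <- (length(k) - 1L) %/% 2L
    n <- d[ax]
    W <- matrix(0, n, n)
    for (o in -r:r) {
      src <- mirror_fold(seq_len(n) + o, n)
      W[cbind(seq_len(n), src)] <- W[cbind(seq_len(n), src)] + k[o + r + 1L]
    }
    a <- apply_axis(a, ax, function(m) W %*% m)
  }
  a
}

gaussian_kernel_1d <- function(sigma, truncate = 4) {
  if (sigma <= 0) return(1)
  r <- max(1L, as.integer(ceiling(truncate * sigma)))
  k <- exp(-0.5 * ((-r:r) / sigma)^2)
  k / sum(k)
}

#' Gaussian smoothing of an n-D image
#'
#' Separable Gaussian filter with mirror boundary handling, routed through the
#' backend dispatch layer.
#'
#' @param img image (array or `image_volume`).
#' @param sigma scalar or per-axis standard deviation in voxels.
#' @param truncate kernel radius in units of sigma.
#' @return smoothed image of the same shape and residence.
#' @export
gaussian_filter <- function(img, sigma, truncate = 4) {
  dispatch("filters.gaussian", img, sigma = sigma, truncate = truncate)
}

.ref_gaussian <- function(x, sigma, truncate = 4) {
  d <- dim(x)
  sigma <- rep_len(sigma, length(d))
  sep_convolve(x, lapply(sigma, gaussian_kernel_1d, truncate = truncate))
}

# Uniform (box) local mean with 'valid' cropping: filter every axis with a
# centred running mean, then drop the half-window margins where the window
# ran off the array.
box_mean_valid <- function(a, w) {
  d <- dim(a)
  if (any(d < w)) stop("window larger than image", call. = FALSE)
  h <- (w - 1L) %/% 2L
  for (ax in seq_along(d)) {
    a <- apply_axis(a, ax, function(m) {
      r <- stats::filter(m, rep(1 / w, w), sides = 2)
      matrix(r, nrow = nrow(m))
    })
  }
  idx <- lapply(d, function(n) (h + 1L):(n - h))
  do.call(`[`, c(list(a), idx, list(drop = FALSE)))
}

# gaussian-weighted local mean with 'valid' cropping (SSIM option)
gauss_mean_valid <- function(a, w, sigma) {
  d <- dim(a)
  if (any(d < w)) stop("window larger than image", call. = FALSE)
  h <- (w - 1L) %/% 2L
  k <- exp(-0.5 * ((-h:h) / sigma)^2)
  k <- k / sum(k)
  for (ax in seq_along(d)) {
    a <- apply_axis(a, ax, function(m) {
      r <- stats::filter(m, k, sides = 2)
      matrix(r, nrow = nrow(m))
    })
  }
  idx <- lapply(d, function(n) (h + 1L):(n - h))
  do.call(`[`, c(list(a), idx, list(drop = FALSE)))
}

## padding ------------------------------------------------------------------

# Pad an array by `before`/`after` voxels per axis with edge replication.
pad_edge <- function(a, before, after = before) {
  d <- dim(a)
  idx <- lapply(seq_along(d), function(ax) {
    pmin(pmax(seq.int(1L - before[ax], d[ax] + after[ax]), 1L), d[ax])
  })
  do.call(`[`, c(list(a), idx, list(drop = FALSE)))
}

crop_center <- function(a, before, target_dim) {
  idx <- lapply(seq_along(target_dim), function(ax) {
    seq.int(before[ax] + 1L, before[ax] + target_dim[ax])
  })
  do.call(`[`, c(list(a), idx, list(drop = FALSE)))
}

## structuring elements -----------------------------------------------------

# Integer offsets of a ball (nd = 3) / disk (nd = 2) of radius r, including
# the centre; isotropic in voxel units.
ball_offsets <- function(r, nd = 3L) {
  r <- as.integer(r)
  ax <- rep(list(-r:r), nd)
  g <- as.matrix(expand.grid(ax))
  colnames(g) <- NULL
  keep <- rowSums(g^2) <= r^2
  storage.mode(g) <- "integer"
  g[keep, , drop = FALSE]
}

# face (+/-1 along each axis) connectivity offsets, centre excluded
face_offsets <- function(nd) {
  out <- matrix(0L, 2L * nd, nd)
  for (a in seq_len(nd)) {
    out[2L * a - 1L, a] <- -1L
    out[2L * a, a] <- 1L
  }
  out
}

# full (box) connectivity offsets, centre excluded
box_offsets <- function(nd) {
  g <- as.matrix(expand.grid(rep(list(-1L:1L), nd)))
  colnames(g) <- NULL
  storage.mode(g) <- "integer"
  g[rowSums(abs(g)) > 0L, , drop = FALSE]
}

## FFT convolution ----------------------------------------------------------

# Circular FFT convolution of x with `psf` whose centre voxel floor(n/2)
# (0-based) is moved to the origin. correlate = TRUE convolves with the
# coordinate-reversed kernel instead.
make_otf <- function(psf, out_dim) {
  d <- dim(psf)
  k <- array(0, out_dim)
  idx <- lapply(seq_along(d), function(ax) {
    src <- seq_len(d[ax])
    ctr <- d[ax] %/% 2L  # 0-based centre
    ((src - 1L - ctr) %% out_dim[ax]) + 1L
  })
  k[as.matrix(do.call(expand.grid, idx))] <-
    psf[as.matrix(do.call(expand.grid, lapply(d, seq_len)))]
  fft(k)
}

fft_convolve <- function(x, otf, correlate = FALSE) {
  if (correlate) otf <- Conj(otf)
  Re(fft(fft(x) * otf, inverse = TRUE)) / length(x)
}
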
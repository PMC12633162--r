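# Independent oracles used to cross-check the package's implementations.
# These deliberately use naive direct formulations (spatial-domain loops,
# exhaustive searches, grids) rather than the optimized code paths.

# direct spatial-domain Richardson-Lucy on an edge-replicated padded canvas
rl_oracle <- function(observed, psf, n_iter, eps = 1e-12) {
  psf <- psf / sum(psf)
  d <- dim(observed)
  nd <- length(d)
  pad <- dim(psf) %/% 2L
  padded <- voxkit:::pad_edge(observed, pad)
  dp <- dim(padded)
  # direct spatial convolution on the padded canvas (periodic indexing: the
  # canvas is the model's domain, matching the padded-boundary definition)
  conv_direct <- function(e, k, correlate = FALSE) {
    dk <- dim(k)
    ctr <- dk %/% 2L  # 0-based centre
    out <- array(0, dim(e))
    kidx <- as.matrix(do.call(expand.grid, lapply(dk, seq_len)))
    eidx <- as.matrix(do.call(expand.grid, lapply(dim(e), seq_len)))
    for (r in seq_len(nrow(kidx))) {
      kv <- k[matrix(kidx[r, ], 1)]
      if (kv == 0) next
      off <- kidx[r, ] - 1L - ctr
      src <- eidx
      for (a in seq_len(nd)) {
        shift <- if (correlate) eidx[, a] + off[a] else eidx[, a] - off[a]
        src[, a] <- ((shift - 1L) %% dim(e)[a]) + 1L
      }
      out <- out + kv * array(e[src], dim(e))
    }
    out
  }
  e <- padded
  for (i in seq_len(n_iter)) {
    c1 <- conv_direct(e, psf)
    ratio <- padded / (c1 + eps)
    # back-convolution with the coordinate-reversed PSF = cross-correlation
    e <- e * conv_direct(ratio, psf, correlate = TRUE)
  }
  voxkit:::crop_center(e, pad, d)
}

# exhaustive between-class-variance Otsu over explicit class statistics
otsu_oracle <- function(x, nbins = 256L) {
  rng <- range(x)
  width <- (rng[2] - rng[1]) / nbins
  bin <- pmin(floor((x - rng[1]) / width) + 1L, nbins)
  centers <- rng[1] + (seq_len(nbins) - 0.5) * width
  best <- -Inf
  best_k <- 1L
  for (k in 1:(nbins - 1L)) {
    lo <- bin <= k
    n0 <- sum(lo); n1 <- length(x) - n0
    if (n0 == 0L || n1 == 0L) next
    w0 <- n0 / length(x)
    m0 <- mean(centers[bin[lo]])
    m1 <- mean(centers[bin[!lo]])
    v <- w0 * (1 - w0) * (m0 - m1)^2
    if (v > best) { best <- v; best_k <- k }
  }
  centers[best_k]
}

# exhaustive two-threshold multi-Otsu over explicit class statistics
multi_otsu_oracle <- function(x, nbins = 256L) {
  rng <- range(x)
  width <- (rng[2] - rng[1]) / nbins
  bin <- pmin(floor((x - rng[1]) / width) + 1L, nbins)
  centers <- rng[1] + (seq_len(nbins) - 0.5) * width
  best <- -Inf; best_ij <- c(1L, 2L)
  n <- length(x)
  for (i in 1:(nbins - 2L)) {
    for (j in (i + 1L):(nbins - 1L)) {
      g1 <- bin <= i; g2 <- bin > i & bin <= j; g3 <- bin > j
      if (!any(g1) || !any(g2) || !any(g3)) next
      v <- sum(g1) / n * mean(centers[bin[g1]])^2 +
           sum(g2) / n * mean(centers[bin[g2]])^2 +
           sum(g3) / n * mean(centers[bin[g3]])^2
      if (v > best) { best <- v; best_ij <- c(i, j) }
    }
  }
  centers[best_ij]
}

# grid-search scale-invariant PSNR: minimize MSE over (alpha, beta) on a grid
sipsnr_oracle <- function(ref, est, n_grid = 401L) {
  rz <- (ref - mean(ref)) / sd(ref)
  a0 <- sum((est - mean(est)) * (rz - mean(rz))) / max(sum((est - mean(est))^2), 1e-30)
  alphas <- seq(a0 - 0.5, a0 + 0.5, length.out = n_grid)
  best <- Inf
  for (a in alphas) {
    b <- mean(rz) - a * mean(est)
    mse <- mean((rz - (a * est + b))^2)
    if (mse < best) best <- mse
  }
  rng <- max(rz) - min(rz)
  10 * log10(rng^2 / best)
}

# small deterministic toy labelings for AP contingency checks
ap_toy <- function() {
  gt <- array(0L, c(1, 10, 10))
  gt[1, 1:5, 1:4] <- 1L   # 20 voxels
  gt[1, 7:9, 6:9] <- 2L   # 12 voxels
  pred <- array(0L, c(1, 10, 10))
  pred[1, 1:3, 1:4] <- 7L # IoU with gt 1 = 12/20 = 0.6
  list(gt = gt, pred = pred)
}
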
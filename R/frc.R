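## Fourier ring / shell correlation ----------------------------------------

#' Fourier ring (2-D) / shell (3-D) correlation between two images
#'
#' For each frequency shell `s` the correlation is
#' `Re(sum(Fa * Conj(Fb))) / sqrt(sum(|Fa|^2) * sum(|Fb|^2))` over the
#' frequency samples whose normalized radius falls in the shell. Shells have
#' unit-bin width on the grid of the smallest axis and extend up to the
#' Nyquist radius (0.5 cycles/pixel); empty shells are dropped.
#'
#' @param img_a,img_b images of identical shape (2-D -> rings, 3-D -> shells).
#' @param criterion,threshold resolution criterion forwarded to
#'   [resolution_from_curve()].
#' @return an object of class `frc_curve` with fields `freqs` (cycles/pixel),
#'   `corr`, `shell_counts` and `resolution` (pixels, `NA` = unresolved).
#' @export
frequency_correlation <- function(img_a, img_b, criterion = "fixed",
                                  threshold = 1 / 7) {
  check_same_shape(img_a, img_b)
  a <- vol_data(img_a)
  b <- vol_data(img_b)
  d <- dim(a)
  if (length(d) < 2L || length(d) > 3L)
    stop("frequency correlation needs a 2-D or 3-D image", call. = FALSE)
  fa <- fft(a)
  fb <- fft(b)
  r2 <- freq_radius_sq(d)
  nref <- min(d)
  shell <- as.integer(round(sqrt(r2) * nref))
  keep <- shell >= 1L & shell <= nref %/% 2L
  num <- tapply(Re(fa * Conj(fb))[keep], shell[keep], sum)
  da <- tapply(abs(fa)[keep]^2, shell[keep], sum)
  db <- tapply(abs(fb)[keep]^2, shell[keep], sum)
  cnt <- tabulate(shell[keep])
  cnt <- cnt[cnt > 0L]
  corr <- as.numeric(num) / sqrt(as.numeric(da) * as.numeric(db))
  corr[!is.finite(corr)] <- 0
  corr <- pmin(1, pmax(-1, corr))
  s <- as.integer(names(num))
  curve <- structure(
    list(freqs = s / nref, corr = corr, shell_counts = as.integer(cnt),
         resolution = NA_real_, criterion = criterion, threshold = threshold),
    class = "frc_curve")
  curve$resolution <- resolution_from_curve(curve, criterion, threshold)
  curve
}

# squared normalized frequency radius for each FFT sample (unshifted layout)
freq_radius_sq <- function(d) {
  fr <- lapply(d, function(n) {
    k <- 0:(n - 1L)
    f <- ifelse(k <= n %/% 2L, k, k - n) / n
    f^2
  })
  r2 <- array(0, d)
  for (ax in seq_along(d)) {
    r2 <- r2 + array(rep(fr[[ax]], each = prod(d[seq_len(ax - 1L)])), d)
  }
  r2
}

#' Estimate resolution from a frequency-correlation curve
#'
#' Finds the first frequency where the correlation falls below the criterion
#' threshold, linearly interpolating between shells; resolution is the inverse
#' of that frequency, in pixels per cycle. `criterion = "fixed"` uses a
#' constant threshold (default 1/7); `"half-bit"` uses the half-bit curve
#' derived from the per-shell sample counts.
#'
#' @param curve an `frc_curve`.
#' @param criterion `"fixed"` or `"half-bit"`.
#' @param threshold constant threshold for the fixed criterion.
#' @return resolution in pixels, or `NA` when the curve never crosses
#'   ("unresolved").
#' @export
resolution_from_curve <- function(curve, criterion = c("fixed", "half-bit"),
                                  threshold = 1 / 7) {
  criterion <- match.arg(criterion)
  f <- curve$freqs
  co <- curve$corr
  thr <- if (criterion == "fixed") rep(threshold, length(f))
  else {
    n <- pmax(curve$shell_counts, 1L)
    (0.2071 + 1.9102 / sqrt(n)) / (1.2071 + 0.9102 / sqrt(n))
  }
  below <- which(co < thr)
  if (!length(below)) return(NA_real_)
  i <- below[1L]
  if (i == 1L) return(1 / f[1L])
  # linear interpolation of the crossing of (corr - thr) between shells
  g1 <- co[i - 1L] - thr[i - 1L]
  g2 <- co[i] - thr[i]
  t <- g1 / (g1 - g2)
  fc <- f[i - 1L] + t * (f[i] - f[i - 1L])
  1 / fc
}

#' Single-image FRC resolution estimate
#'
#' Splits one 2-D image into two half-resolution sub-images by checkerboard
#' decimation (the two diagonal pixel classes), computes the FRC between them,
#' and rescales the frequency axis by the 0.5 decimation factor so the curve
#' reads in original-pixel units. Odd dimensions are trimmed with a warning.
#' 3-D volumes use the central Z-plane.
#'
#' @param img 2-D image (or 3-D volume; central plane used).
#' @inheritParams frequency_correlation
#' @return an `frc_curve` (frequencies in original-image cycles/pixel).
#' @export
single_image_frc <- function(img, criterion = "fixed", threshold = 1 / 7) {
  x <- vol_data(img)
  d <- dim(x)
  if (length(d) == 3L) x <- x[(d[1L] + 1L) %/% 2L, , , drop = TRUE]
  d <- dim(x)
  if (any(d %% 2L == 1L)) {
    warning("odd image dimensions trimmed for checkerboard split")
    x <- x[seq_len(d[1L] - d[1L] %% 2L), seq_len(d[2L] - d[2L] %% 2L)]
    d <- dim(x)
  }
  odd1 <- seq(1L, d[1L], by = 2L)
  odd2 <- seq(1L, d[2L], by = 2L)
  sub_a <- x[odd1, odd2]
  sub_b <- x[odd1 + 1L, odd2 + 1L]
  curve <- frequency_correlation(sub_a, sub_b, criterion, threshold)
  curve$freqs <- curve$freqs * 0.5
  curve$resolution <- resolution_from_curve(curve, criterion, threshold)
  curve
}

#' @export
print.frc_curve <- function(x, ...) {
  cat(sprintf("<frc_curve> %d shells, freq %.3f..%.3f cycles/px\n",
              length(x$freqs), min(x$freqs), max(x$freqs)))
  if (is.na(x$resolution)) cat("  resolution: unresolved\n")
  else cat(sprintf("  resolution: %.2f px (criterion %s)\n",
                   x$resolution, x$criterion))
  invisible(x)
}

#' @export
plot.frc_curve <- function(x, ...) {
  plot(x$freqs, x$corr, type = "l", xlab = "spatial frequency (cycles/px)",
       ylab = "correlation", ylim = c(min(0, min(x$corr)), 1), ...)
  graphics::abline(h = x$threshold, lty = 2)
  invisible(x)
}

#' @export
as.data.frame.frc_curve <- function(x, ...) {
  data.frame(freq = x$freqs, corr = x$corr, n = x$shell_counts)
}
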
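## Image quality metrics ----------------------------------------------------

check_same_shape <- function(a, b) {
  if (!identical(dim(vol_data(a)), dim(vol_data(b))))
    stop("images must have identical shapes", call. = FALSE)
}

#' Peak signal-to-noise ratio
#'
#' `10 * log10(data_range^2 / MSE)` in decibels; identical inputs (MSE = 0)
#' return `Inf`. Swapping `ref` and `est` changes the value only through the
#' choice of `data_range`.
#'
#' @param ref,est images of identical shape.
#' @param data_range positive dynamic range of the reference.
#' @return PSNR in dB.
#' @export
psnr <- function(ref, est, data_range) {
  check_same_shape(ref, est)
  stopifnot(data_range > 0)
  mse <- mean((vol_data(ref) - vol_data(est))^2)
  if (mse == 0) return(Inf)
  10 * log10(data_range^2 / mse)
}

#' Scale-invariant peak signal-to-noise ratio
#'
#' The reference is standardized to zero mean and unit variance; the estimate
#' is then matched to it by the closed-form least-squares affine map
#' `est' = alpha * est + beta`, and PSNR is computed between the standardized
#' reference and `est'` with `data_range = max - min` of the standardized
#' reference. The result is invariant under any positive affine transform of
#' the estimate. A constant estimate uses the beta-only fit (alpha = 0).
#'
#' @param ref,est images of identical shape; `ref` must be non-constant.
#' @return si-PSNR in dB (`Inf` when the fit is exact).
#' @export
scale_invariant_psnr <- function(ref, est) {
  check_same_shape(ref, est)
  r <- as.vector(vol_data(ref))
  e <- as.vector(vol_data(est))
  sr <- sd(r)
  if (sr == 0) stop("reference has zero variance", call. = FALSE)
  rz <- (r - mean(r)) / sr
  ve <- sum((e - mean(e))^2)
  alpha <- if (ve > 0) sum((e - mean(e)) * (rz - mean(rz))) / ve else 0
  beta <- mean(rz) - alpha * mean(e)
  fit <- alpha * e + beta
  rng <- max(rz) - min(rz)
  mse <- mean((rz - fit)^2)
  if (mse <= .Machine$double.eps * 100) return(Inf)
  10 * log10(rng^2 / mse)
}

#' Structural similarity index (2-D and 3-D)
#'
#' Mean local SSIM with the standard luminance/contrast/structure form and
#' stabilizers `C1 = (0.01 * data_range)^2`, `C2 = (0.03 * data_range)^2`.
#' Local statistics use an n-D sliding window (uniform by default, Gaussian
#' with `sigma` when `gaussian = TRUE`) and 'valid' cropping, so the window
#' must fit inside every spatial dimension. Symmetric in its two arguments.
#'
#' @param ref,est images of identical shape.
#' @param data_range positive dynamic range.
#' @param window odd window width in voxels (default 7).
#' @param gaussian use a Gaussian-weighted window instead of uniform.
#' @param sigma Gaussian window sigma.
#' @return mean SSIM in `[-1, 1]`.
#' @export
ssim <- function(ref, est, data_range, window = 7L, gaussian = FALSE,
                 sigma = 1.5) {
  check_same_shape(ref, est)
  stopifnot(data_range > 0, window %% 2L == 1L)
  x <- vol_data(ref)
  y <- vol_data(est)
  if (any(dim(x) < window))
    stop("window larger than image", call. = FALSE)
  loc <- if (gaussian) function(a) gauss_mean_valid(a, window, sigma)
         else function(a) box_mean_valid(a, window)
  mu1 <- loc(x); mu2 <- loc(y)
  s11 <- loc(x * x) - mu1^2
  s22 <- loc(y * y) - mu2^2
  s12 <- loc(x * y) - mu1 * mu2
  c1 <- (0.01 * data_range)^2
  c2 <- (0.03 * data_range)^2
  num <- (2 * mu1 * mu2 + c1) * (2 * s12 + c2)
  den <- (mu1^2 + mu2^2 + c1) * (s11 + s22 + c2)
  mean(num / den)
}
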
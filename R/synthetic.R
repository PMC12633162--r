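## Seeded synthetic phantoms -----------------------------------------------
##
## Every generator takes an explicit integer seed and restores the caller's
## random state afterwards, so fixtures are bit-reproducible and no global
## state leaks.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Specification of a synthetic phantom
#'
#' @param shape axis sizes (ZYX).
#' @param n_objects number of objects (spheres / cells).
#' @param radius_range min/max object radius in voxels (min >= 2); objects
#'   must fit inside the volume with a 2-voxel margin.
#' @param intensity foreground intensity added on top of background.
#' @param background background level.
#' @param noise_sigma additive Gaussian noise standard deviation.
#' @param poisson apply Poisson (shot) noise.
#' @param poisson_peak expected photon count at `background + intensity` when
#'   Poisson noise is on.
#' @param seed integer random seed; fixed seed gives bit-identical output.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(32L, 64L, 64L), n_objects = 4L,
                         radius_range = c(5, 9), intensity = 1,
                         background = 0.1, noise_sigma = 0.01,
                         poisson = FALSE, poisson_peak = 200, seed = 1L) {
  shape <- as.integer(shape)
  stopifnot(length(radius_range) == 2L, radius_range[1L] >= 2,
            radius_range[2L] >= radius_range[1L], n_objects >= 0L,
            poisson_peak > 0)
  structure(list(shape = shape, n_objects = as.integer(n_objects),
                 radius_range = radius_range, intensity = intensity,
                 background = background, noise_sigma = noise_sigma,
                 poisson = poisson, poisson_peak = poisson_peak,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

apply_noise <- function(img, spec) {
  if (isTRUE(spec$poisson)) {
    scale <- spec$poisson_peak / (spec$background + spec$intensity)
    img <- array(rpois(length(img), lambda = pmax(img, 0) * scale) / scale,
                 dim(img))
  }
  if (spec$noise_sigma > 0)
    img <- img + array(rnorm(length(img), sd = spec$noise_sigma), dim(img))
  img
}

# rejection-sample n centres with pairwise surface gap >= 2 voxels (or
# touching when requested) and a margin of radius + 2 from every face
sample_centers <- function(shape, n, radii, min_gap = 2, max_tries = 10000L) {
  nd <- length(shape)
  if (n > 0L && any(shape < 2 * max(radii) + 5))
    stop("objects do not fit inside the volume with a 2-voxel margin",
         call. = FALSE)
  centers <- matrix(NA_real_, n, nd)
  tries <- 0L
  i <- 1L
  while (i <= n) {
    tries <- tries + 1L
    if (tries > max_tries)
      stop("capacity error: could not place ", n, " objects in ",
           max_tries, " attempts", call. = FALSE)
    c_i <- sapply(seq_len(nd), function(a)
      runif(1, radii[i] + 3, shape[a] - radii[i] - 2))
    ok <- TRUE
    if (i > 1L) {
      for (j in seq_len(i - 1L)) {
        if (sqrt(sum((c_i - centers[j, ])^2)) <
            radii[i] + radii[j] + min_gap) { ok <- FALSE; break }
      }
    }
    if (ok) { centers[i, ] <- c_i; i <- i + 1L }
  }
  centers
}

# fill a sphere (scalar radius) or axis-aligned ellipsoid (per-axis radii)
fill_sphere <- function(labels, center, radius, id) {
  d <- dim(labels)
  radius <- rep_len(radius, length(d))
  lo <- pmax(1L, floor(center - radius))
  hi <- pmin(d, ceiling(center + radius))
  idx <- lapply(seq_along(d), function(a) lo[a]:hi[a])
  g <- as.matrix(do.call(expand.grid, idx))
  r2 <- rowSums(sweep(sweep(g, 2L, center), 2L, radius, `/`)^2)
  inside <- g[r2 <= 1, , drop = FALSE]
  labels[inside] <- id
  labels
}

#' Nuclei-like phantom: bright spheres with ground-truth labels
#'
#' Places `n_objects` non-overlapping spheres (rejection-sampled centres with
#' a 2-voxel surface gap) on a constant background, adds seeded noise, and
#' returns the image together with the exact instance labels.
#'
#' @param spec a [phantom_spec()].
#' @param touching allow spheres to touch (gap 0) to exercise watershed
#'   splitting.
#' @return list with `image` (numeric array) and `labels` (integer array).
#' @export
make_nuclei_phantom <- function(spec = phantom_spec(), touching = FALSE) {
  with_seed(spec$seed, {
    d <- spec$shape
    labels <- array(0L, d)
    if (spec$n_objects > 0L) {
      radii <- runif(spec$n_objects, spec$radius_range[1L],
                     spec$radius_range[2L])
      centers <- sample_centers(d, spec$n_objects, radii,
                                min_gap = if (touching) 0 else 2)
      for (i in seq_len(spec$n_objects))
        labels <- fill_sphere(labels, centers[i, ], radii[i], i)
    }
    img <- spec$background + spec$intensity * (labels > 0L)
    img <- apply_noise(img, spec)
    list(image = array(img, d), labels = labels)
  })
}

#' Monolayer phantom: Voronoi cells, membrane ridges, nuclei and mitochondria
#'
#' Nucleus centres are sampled in the XY plane (pairwise separation at least
#' `2 * max radius + 2`); the ground-truth cells are the XY Voronoi partition
#' of those centres extruded over a central Z-slab; the membrane channel has
#' bright ridges on the cell boundaries (and the slab faces) blurred with
#' sigma 1; the DNA channel contains the nucleus spheres (clipped to their
#' own cell, so every nucleus lies inside its cell); the mitochondria channel
#' carries smooth interior texture. Seeded noise is added to all channels.
#'
#' @param spec a [phantom_spec()]; `shape` is ZYX, `n_objects` the cell count.
#' @return list with `membrane`, `mito`, `dna` (numeric arrays) and
#'   `nuclei_gt`, `cells_gt` (integer label arrays).
#' @export
make_monolayer_phantom <- function(spec = phantom_spec(
    shape = c(32L, 128L, 128L), n_objects = 6L, radius_range = c(10, 12),
    noise_sigma = 0.02)) {
  with_seed(spec$seed, {
    d <- spec$shape
    nz <- d[1L]; ny <- d[2L]; nx <- d[3L]
    n <- spec$n_objects
    rmax <- spec$radius_range[2L]
    radii <- runif(n, spec$radius_range[1L], spec$radius_range[2L])
    cent_xy <- sample_centers(c(ny, nx), n, rep(rmax, n), min_gap = 2)
    zlo <- max(1L, round(0.2 * nz)); zhi <- min(nz, round(0.8 * nz))
    zc <- (zlo + zhi) / 2
    # XY Voronoi assignment
    yy <- matrix(seq_len(ny), ny, nx)
    xx <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
    d2 <- sapply(seq_len(n), function(i)
      (yy - cent_xy[i, 1L])^2 + (xx - cent_xy[i, 2L])^2)
    vor <- array(max.col(-d2, ties.method = "first"), c(ny, nx))
    cells_gt <- array(0L, d)
    for (z in zlo:zhi) cells_gt[z, , ] <- vor
    # membrane ridges: XY Voronoi boundaries within the slab + slab faces
    bound <- (vor != rbind(vor[-1L, ], vor[ny, ])) |
             (vor != cbind(vor[, -1L], vor[, nx]))
    mem <- array(0, d)
    for (z in zlo:zhi) mem[z, , ] <- bound
    mem[zlo, , ] <- 1
    mem[zhi, , ] <- 1
    mem <- .ref_gaussian(mem, sigma = 1)
    mem <- mem / max(mem)
    # nuclei as ellipsoids at the slab centre (Z semi-axis clipped to the
    # slab), restricted to their own cell so containment holds exactly
    nuclei_gt <- array(0L, d)
    rz <- pmin(radii, (zhi - zlo) / 2 - 1)
    for (i in seq_len(n)) {
      nuclei_gt <- fill_sphere(nuclei_gt,
                               c(zc, cent_xy[i, 1L], cent_xy[i, 2L]),
                               c(rz[i], radii[i], radii[i]), i)
    }
    nuclei_gt[nuclei_gt > 0L & cells_gt != nuclei_gt] <- 0L
    dna <- spec$background + spec$intensity * (nuclei_gt > 0L)
    # interior texture for mitochondria: smooth noise inside the slab
    tex <- .ref_gaussian(array(runif(prod(d)), d), sigma = 2)
    tex <- (tex - min(tex)) / max(1e-12, diff(range(tex)))
    mito <- spec$background + 0.6 * spec$intensity * tex * (cells_gt > 0L)
    membrane <- spec$background + spec$intensity * mem
    list(membrane = array(apply_noise(membrane, spec), d),
         mito = array(apply_noise(mito, spec), d),
         dna = array(apply_noise(dna, spec), d),
         nuclei_gt = nuclei_gt, cells_gt = cells_gt)
  })
}

#' Separable Gaussian point spread function
#'
#' Unit-sum Gaussian centred at `floor(n/2)` (0-based) per axis; symmetric
#' under coordinate reversal for odd shapes.
#'
#' @param shape axis sizes.
#' @param sigmas per-axis standard deviation in voxels (> 0).
#' @return numeric array summing to 1.
#' @export
make_gaussian_psf <- function(shape = c(9L, 13L, 13L), sigmas = c(1, 2, 2)) {
  shape <- as.integer(shape)
  sigmas <- rep_len(sigmas, length(shape))
  stopifnot(all(sigmas > 0))
  axes <- lapply(seq_along(shape), function(a) {
    x <- seq_len(shape[a]) - 1L - shape[a] %/% 2L
    exp(-0.5 * (x / sigmas[a])^2)
  })
  psf <- Reduce(`%o%`, axes)
  psf <- array(psf, shape)
  psf / sum(psf)
}

#' Degrade a ground-truth image: PSF blur plus seeded noise
#'
#' Convolves with the PSF using the same edge-replicated padded FFT
#' convolution as the deconvolution module, then applies seeded Poisson
#' and/or Gaussian noise.
#'
#' @param truth ground-truth image (array or `image_volume`).
#' @param psf point spread function (same rank).
#' @param noise list with optional `poisson` (logical), `poisson_peak`,
#'   `gaussian_sigma`.
#' @param seed integer seed.
#' @return degraded image, same shape as `truth`.
#' @export
degrade <- function(truth, psf, noise = list(poisson = TRUE,
                                             poisson_peak = 200,
                                             gaussian_sigma = 0),
                    seed = 1L) {
  x <- vol_data(truth)
  p <- vol_data(psf)
  if (length(dim(x)) != length(dim(p)))
    stop("PSF rank must match image rank", call. = FALSE)
  p <- p / sum(p)
  pad <- dim(p) %/% 2L
  xp <- pad_edge(x, pad)
  blurred <- crop_center(fft_convolve(xp, make_otf(p, dim(xp))), pad, dim(x))
  blurred[blurred < 0] <- 0
  with_seed(seed, {
    out <- blurred
    if (isTRUE(noise$poisson)) {
      pk <- if (is.null(noise$poisson_peak)) 200 else noise$poisson_peak
      scale <- pk / max(out)
      out <- array(rpois(length(out), out * scale) / scale, dim(out))
    }
    gs <- if (is.null(noise$gaussian_sigma)) 0 else noise$gaussian_sigma
    if (gs > 0) out <- out + array(rnorm(length(out), sd = gs), dim(out))
    rewrap(array(out, dim(x)), truth)
  })
}

#' Band-limited random field
#'
#' White noise low-pass filtered with a hard radial cutoff in frequency
#' space; spectral power above the cutoff is zero by construction.
#'
#' @param shape axis sizes (2-D or 3-D).
#' @param cutoff radial cutoff in cycles/pixel, in (0, 0.5].
#' @param seed integer seed.
#' @return numeric array (zero mean, unit variance after filtering).
#' @export
make_band_limited <- function(shape = c(128L, 128L), cutoff = 0.25,
                              seed = 1L) {
  stopifnot(cutoff > 0, cutoff <= 0.5)
  shape <- as.integer(shape)
  with_seed(seed, {
    x <- array(rnorm(prod(shape)), shape)
    f <- fft(x)
    r <- sqrt(freq_radius_sq(shape))
    f[r > cutoff] <- 0
    y <- Re(fft(f, inverse = TRUE)) / prod(shape)
    y <- (y - mean(y)) / sd(y)
    array(y, shape)
  })
}
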
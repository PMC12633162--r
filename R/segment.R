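## Two-stage 3-D monolayer segmentation ------------------------------------
##
## Stage 1 finds nuclei in the DNA channel (downscale, median filter, Otsu,
## hole filling, distance-transform watershed, upscale, size filter); stage 2
## grows whole cells from eroded nuclear seeds by seeded watershed on the
## membrane signal, restricted to a monolayer mask built from the combined
## channels.

#' Configuration of the monolayer segmentation pipeline
#'
#' Every numeric parameter of the two-stage pipeline, with the reference
#' defaults. Radii are isotropic in voxel units ("ball" = 3-D, "disk" = 2-D
#' applied slicewise); an anisotropic correction can be expressed through
#' `spacing`.
#'
#' @param nuclei_downscale isotropic downscale factor for the nuclei stage.
#' @param median_ball_radius ball radius (px) of the median filter.
#' @param hole_area_threshold holes below this area (px, per Z-slice) are
#'   filled.
#' @param nuclei_watershed_ball_radius ball footprint radius (px) for distance
#'   map maxima seeding the nuclei watershed.
#' @param nuclei_min_size minimum nucleus size (px) after upscaling.
#' @param membrane_otsu_classes classes of the multi-Otsu membrane threshold.
#' @param closing_disk_radius disk radius (px) of the slicewise morphological
#'   closing of the monolayer mask.
#' @param mask_downscale resolution at which the mask closing runs.
#' @param seed_erosion_ball_radius ball radius (px) eroding nuclei into seeds.
#' @param cell_watershed_ball_radius ball footprint radius (px) for the cell
#'   watershed (maxima detection when run without markers).
#' @param cell_min_size minimum cell size (px).
#' @param spacing per-axis voxel spacing for the distance transform.
#' @return an object of class `monolayer_config`.
#' @export
monolayer_config <- function(nuclei_downscale = 0.5,
                             median_ball_radius = 5L,
                             hole_area_threshold = 20L,
                             nuclei_watershed_ball_radius = 10L,
                             nuclei_min_size = 50L,
                             membrane_otsu_classes = 3L,
                             closing_disk_radius = 17L,
                             mask_downscale = 0.25,
                             seed_erosion_ball_radius = 5L,
                             cell_watershed_ball_radius = 8L,
                             cell_min_size = 100L,
                             spacing = c(1, 1, 1)) {
  cfg <- list(nuclei_downscale = nuclei_downscale,
              median_ball_radius = as.integer(median_ball_radius),
              hole_area_threshold = as.integer(hole_area_threshold),
              nuclei_watershed_ball_radius =
                as.integer(nuclei_watershed_ball_radius),
              nuclei_min_size = as.integer(nuclei_min_size),
              membrane_otsu_classes = as.integer(membrane_otsu_classes),
              closing_disk_radius = as.integer(closing_disk_radius),
              mask_downscale = mask_downscale,
              seed_erosion_ball_radius = as.integer(seed_erosion_ball_radius),
              cell_watershed_ball_radius =
                as.integer(cell_watershed_ball_radius),
              cell_min_size = as.integer(cell_min_size),
              spacing = spacing)
  radii <- cfg[grepl("radius", names(cfg))]
  if (any(unlist(radii) < 1L)) stop("all radii must be >= 1", call. = FALSE)
  if (cfg$nuclei_downscale <= 0 || cfg$nuclei_downscale > 1 ||
      cfg$mask_downscale <= 0 || cfg$mask_downscale > 1)
    stop("downscale factors must be in (0, 1]", call. = FALSE)
  if (cfg$nuclei_min_size < 1L || cfg$cell_min_size < 1L)
    stop("minimum sizes must be >= 1", call. = FALSE)
  if (cfg$membrane_otsu_classes < 2L)
    stop("otsu classes must be >= 2", call. = FALSE)
  structure(cfg, class = "monolayer_config")
}

#' @export
print.monolayer_config <- function(x, ...) {
  cat("<monolayer_config>\n")
  for (nm in setdiff(names(x), "spacing"))
    cat(sprintf("  %-30s %s\n", nm, format(x[[nm]])))
  cat(sprintf("  %-30s %s\n", "spacing", paste(x$spacing, collapse = "x")))
  invisible(x)
}

#' Robust percentile normalization of a fluorescence channel
#'
#' Rescales intensities to `[0, 1]` by a 0.1-99.9 percentile stretch with
#' clipping; the mapping is monotone and invariant to affine transforms of
#' the input. A constant image returns all zeros with a warning.
#'
#' @param img image (array or `image_volume`).
#' @param probs lower/upper stretch percentiles.
#' @return normalized image in `[0, 1]`.
#' @export
normalize_channel <- function(img, probs = c(0.001, 0.999)) {
  with_data(img, function(x) {
    q <- quantile(x, probs, names = FALSE, type = 7)
    if (q[2L] <= q[1L]) {
      warning("constant image: normalization returns zeros")
      return(array(0, dim(x)))
    }
    y <- (x - q[1L]) / (q[2L] - q[1L])
    y[y < 0] <- 0
    y[y > 1] <- 1
    y
  })
}

#' Otsu threshold (two classes)
#'
#' Maximizes the between-class variance over a `nbins`-bin histogram;
#' equivalent to exhaustive search over all bin-edge thresholds. Returns the
#' threshold as the centre of the selected bin.
#'
#' @param img image (array or `image_volume`); must be non-constant.
#' @param nbins number of histogram bins.
#' @return scalar threshold.
#' @export
otsu_threshold <- function(img, nbins = 256L) {
  x <- as.vector(vol_data(img))
  rng <- range(x)
  if (rng[1L] == rng[2L])
    stop("degenerate histogram: constant image", call. = FALSE)
  h <- hist_counts(x, rng, nbins)
  centers <- h$centers
  w <- h$counts / sum(h$counts)
  mu <- centers * w
  w0 <- cumsum(w)[-nbins]
  m0 <- cumsum(mu)[-nbins]
  mt <- sum(mu)
  w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  bcv <- rep(-Inf, nbins - 1L)
  bcv[valid] <- (mt * w0[valid] - m0[valid])^2 / (w0[valid] * w1[valid])
  k <- which.max(bcv)
  # threshold at the centre of the last bin of the lower class (pixels with
  # value > threshold are foreground)
  centers[k]
}

#' Multi-Otsu thresholds (2 or 3 classes)
#'
#' Exhaustive maximization of the between-class variance over all bin-pair
#' splits of the histogram.
#'
#' @inheritParams otsu_threshold
#' @param classes number of classes (2 or 3).
#' @return numeric vector of `classes - 1` ascending thresholds.
#' @export
multi_otsu <- function(img, classes = 3L, nbins = 256L) {
  classes <- as.integer(classes)
  if (classes == 2L) return(otsu_threshold(img, nbins))
  if (classes != 3L)
    stop("multi_otsu supports 2 or 3 classes", call. = FALSE)
  x <- as.vector(vol_data(img))
  rng <- range(x)
  if (rng[1L] == rng[2L])
    stop("degenerate histogram: constant image", call. = FALSE)
  h <- hist_counts(x, rng, nbins)
  w <- h$counts / sum(h$counts)
  mu <- h$centers * w
  W <- cumsum(w)
  M <- cumsum(mu)
  csum <- function(i, j) { # class weight/mean-sum over bins (i+1)..j
    wij <- W[j] - if (i > 0L) W[i] else 0
    mij <- M[j] - if (i > 0L) M[i] else 0
    c(wij, mij)
  }
  best <- -Inf
  best_ij <- c(1L, 2L)
  for (i in 1:(nbins - 2L)) {
    wi <- W[i]; mi <- M[i]
    if (wi <= 0) next
    js <- (i + 1L):(nbins - 1L)
    w2 <- W[js] - wi
    m2 <- M[js] - mi
    w3 <- W[nbins] - W[js]
    m3 <- M[nbins] - M[js]
    ok <- w2 > 0 & w3 > 0
    if (!any(ok)) next
    v <- rep(-Inf, length(js))
    v[ok] <- mi^2 / wi + m2[ok]^2 / w2[ok] + m3[ok]^2 / w3[ok]
    jbest <- which.max(v)
    if (v[jbest] > best) {
      best <- v[jbest]
      best_ij <- c(i, js[jbest])
    }
  }
  h$centers[best_ij]
}

hist_counts <- function(x, rng, nbins) {
  width <- (rng[2L] - rng[1L]) / nbins
  idx <- pmin(floor((x - rng[1L]) / width) + 1L, nbins)
  list(counts = tabulate(idx, nbins),
       centers = rng[1L] + (seq_len(nbins) - 0.5) * width)
}

#' Segment nuclei from the DNA channel
#'
#' Runs, in order: percentile normalization, downscaling, median filtering
#' with a ball structuring element, Otsu binarization, slicewise hole filling
#' below the area threshold, distance-transform seeded watershed with
#' ball-footprint maxima, order-0 upscaling of the labels to the input shape,
#' size filtering and canonical relabelling.
#'
#' @param dna 3-D single-channel volume (array or `image_volume`).
#' @param cfg a [monolayer_config()].
#' @param keep_steps also return every intermediate mask/stage (attribute
#'   `"steps"`).
#' @return integer label array (0 = background, labels 1..n canonical).
#' @export
segment_nuclei <- function(dna, cfg = monolayer_config(), keep_steps = FALSE) {
  x <- vol_data(dna)
  if (length(dim(x)) != 3L)
    stop("segment_nuclei expects a 3-D single-channel volume", call. = FALSE)
  steps <- list()
  norm <- vol_data(normalize_channel(x))
  small <- vol_data(.ref_rescale(norm, cfg$nuclei_downscale, order = 1L,
                                 anti_aliasing = TRUE))
  med <- .ref_median(small, cfg$median_ball_radius)
  if (min(med) == max(med)) {
    out <- array(0L, dim(x))
    return(out)
  }
  thr <- otsu_threshold(med)
  mask <- array(med > thr, dim(med))
  if (!any(mask)) return(array(0L, dim(x)))
  mask <- fill_holes(mask, cfg$hole_area_threshold)
  edt <- .ref_edt(mask, spacing = cfg$spacing)
  markers <- watershed_markers(edt, mask, cfg$nuclei_watershed_ball_radius)
  ws <- .ref_watershed(-edt, markers, mask)
  up <- .ref_rescale(array(as.double(ws), dim(ws)), factor = 1,
                     order = 0L, anti_aliasing = FALSE,
                     output_shape = dim(x))
  up <- array(as.integer(round(up)), dim(x))
  labels <- size_filter(up, cfg$nuclei_min_size, relabel = TRUE)
  if (keep_steps) {
    steps <- list(normalized = norm, downscaled = small, median = med,
                  threshold = thr, mask = mask, distance = edt,
                  markers = markers, watershed = ws, upscaled = up)
    attr(labels, "steps") <- steps
  }
  labels
}

#' Segment whole cells by seeded watershed on the membrane channel
#'
#' Runs: 3-class multi-Otsu on the normalized membrane channel (lowest class
#' = background) with slicewise hole removal; monolayer mask built from the
#' voxelwise maximum of the three normalized channels, binarized by Otsu,
#' closed with a disk (slicewise) at reduced resolution and upscaled back;
#' seeds from ball-eroded nuclei; seeded watershed on the membrane signal
#' (watershed lines form on the bright membrane ridges) restricted to the
#' monolayer mask; size filtering and canonical relabelling. Every returned
#' cell contains at least one voxel of its seeding nucleus.
#'
#' @param membrane,mito,dna channel volumes sharing one spatial shape.
#' @param nuclei nucleus label array from [segment_nuclei()].
#' @param cfg a [monolayer_config()].
#' @param keep_steps also return intermediate masks (attribute `"steps"`).
#' @return integer label array of cells.
#' @export
segment_cells <- function(membrane, mito, dna, nuclei,
                          cfg = monolayer_config(), keep_steps = FALSE) {
  mem <- vol_data(membrane)
  mit <- vol_data(mito)
  dn <- vol_data(dna)
  nuc <- vol_data(nuclei)
  if (!identical(dim(mem), dim(mit)) || !identical(dim(mem), dim(dn)) ||
      !identical(dim(mem), dim(nuc)))
    stop("all channels and nuclei must share one shape", call. = FALSE)
  if (max(nuc) == 0L) return(array(0L, dim(mem)))
  mem_n <- vol_data(normalize_channel(mem))
  mit_n <- vol_data(normalize_channel(mit))
  dna_n <- vol_data(normalize_channel(dn))
  th <- multi_otsu(mem_n, cfg$membrane_otsu_classes)
  mem_fg <- array(mem_n >= th[1L], dim(mem))
  mem_fg <- fill_holes(mem_fg, cfg$hole_area_threshold)
  combined <- pmax(mem_n, mit_n, dna_n)
  comb_mask <- array(combined > otsu_threshold(combined), dim(mem)) | mem_fg
  small <- vol_data(.ref_rescale(array(as.double(comb_mask), dim(comb_mask)),
                                 cfg$mask_downscale, order = 0L,
                                 anti_aliasing = FALSE)) > 0.5
  small <- array(small, as.integer(round(dim(comb_mask) * cfg$mask_downscale)))
  closed <- close_slicewise(small, cfg$closing_disk_radius)
  mask <- vol_data(.ref_rescale(array(as.double(closed), dim(closed)),
                                factor = 1, order = 0L, anti_aliasing = FALSE,
                                output_shape = dim(mem))) > 0.5
  mask <- array(mask, dim(mem))
  seed_mask <- .ref_erosion(nuc > 0L, cfg$seed_erosion_ball_radius)
  seeds <- array(ifelse(seed_mask, nuc, 0L), dim(mem))
  mask <- mask | seeds > 0L
  cells <- .ref_watershed(mem_n, seeds, mask)
  cells <- size_filter(cells, cfg$cell_min_size, relabel = TRUE)
  if (keep_steps) {
    attr(cells, "steps") <- list(membrane_norm = mem_n,
                                 membrane_thresholds = th,
                                 membrane_fg = mem_fg, combined = combined,
                                 monolayer_mask = mask, seeds = seeds)
  }
  cells
}

# slicewise morphological closing with a disk (2-D structuring element)
close_slicewise <- function(mask, radius) {
  d <- dim(mask)
  for (z in seq_len(d[1L])) {
    mask[z, , ] <- .ref_closing(mask[z, , ], radius)
  }
  mask
}

#' Run the full two-stage monolayer pipeline
#'
#' @param volume 4-D CZYX array (channels: membrane, mitochondria, DNA) or a
#'   list with elements `membrane`, `mito`, `dna`.
#' @param cfg a [monolayer_config()].
#' @return list of class `segmentation_result` with `nuclei`, `cells`
#'   (label arrays) and `stage_timings` (data.frame step/seconds).
#' @export
segment_monolayer <- function(volume, cfg = monolayer_config()) {
  if (is.list(volume) && !is_image_volume(volume)) {
    mem <- volume$membrane; mit <- volume$mito; dn <- volume$dna
  } else {
    v <- vol_data(volume)
    if (length(dim(v)) != 4L)
      stop("expected CZYX volume with 3 channels", call. = FALSE)
    mem <- v[1L, , , ]; mit <- v[2L, , , ]; dn <- v[3L, , , ]
  }
  timings <- list()
  t0 <- proc.time()[["elapsed"]]
  nuclei <- segment_nuclei(dn, cfg)
  timings$nuclei <- proc.time()[["elapsed"]] - t0
  t0 <- proc.time()[["elapsed"]]
  cells <- segment_cells(mem, mit, dn, nuclei, cfg)
  timings$cells <- proc.time()[["elapsed"]] - t0
  structure(list(nuclei = nuclei, cells = cells,
                 stage_timings = data.frame(step = names(timings),
                                            seconds = unlist(timings))),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("<segmentation_result> %d nuclei, %d cells\n",
              max(x$nuclei), max(x$cells)))
  print(x$stage_timings, row.names = FALSE)
  invisible(x)
}

#' Compare two instance segmentations
#'
#' Reports AP over an IoU threshold sweep plus PSNR and SSIM between the
#' intensity image masked by each segmentation's foreground (higher masked
#' PSNR/SSIM = closer spatial agreement).
#'
#' @param a,b integer label arrays.
#' @param intensity intensity image of the same shape.
#' @param iou_thresholds IoU sweep.
#' @return list with `ap` (data.frame from [average_precision()]),
#'   `masked_psnr`, `masked_ssim`.
#' @export
compare_segmentations <- function(a, b, intensity,
                                  iou_thresholds = seq(0.5, 0.95, 0.05)) {
  a <- vol_data(a); b <- vol_data(b); intensity <- vol_data(intensity)
  check_same_shape(a, intensity)
  check_same_shape(a, b)
  ap <- average_precision(a, b, iou_thresholds)
  rng <- max(intensity) - min(intensity)
  if (rng <= 0) rng <- 1
  ia <- intensity * (a > 0L)
  ib <- intensity * (b > 0L)
  list(ap = ap,
       masked_psnr = psnr(ia, ib, data_range = rng),
       masked_ssim = ssim(ia, ib, data_range = rng,
                          window = min(7L, min(dim(a)) -
                                         (1L - min(dim(a)) %% 2L))))
}
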
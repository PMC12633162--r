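## Mirrored n-D image operations (reference backend implementations plus the
## dispatch-routed user-facing wrappers).

as_mask <- function(x) {
  x <- vol_data(x)
  if (is.logical(x)) return(x)
  array(x > 0, dim(x))
}

#' Median filter with a ball/disk footprint
#'
#' @param img image (array or `image_volume`).
#' @param radius footprint radius in voxels (ball in 3-D, disk in 2-D).
#' @return filtered image, same shape; borders use nearest-voxel padding.
#' @export
median_filter <- function(img, radius) {
  dispatch("filters.median", img, radius = radius)
}

.ref_median <- function(x, radius) {
  d <- dim(x)
  off <- ball_offsets(radius, length(d))
  array(cpp_median_filter(as.double(x), as.integer(d), off), d)
}

#' Label connected components
#'
#' @param mask logical (or numeric, thresholded at > 0) array.
#' @param connectivity `"face"` (orthogonal neighbours) or `"full"`.
#' @return integer array of labels, 0 = background.
#' @export
label_components <- function(mask, connectivity = c("face", "full")) {
  connectivity <- match.arg(connectivity)
  dispatch("measure.label", mask, connectivity = connectivity)
}

.ref_label <- function(x, connectivity = "face") {
  m <- as_mask(x)
  d <- dim(m)
  off <- if (identical(connectivity, "full")) box_offsets(length(d))
         else face_offsets(length(d))
  array(cpp_label(m, as.integer(d), off), d)
}

#' Euclidean distance transform
#'
#' Distance from every foreground voxel to the nearest background voxel.
#'
#' @param mask logical array (TRUE = foreground).
#' @param spacing per-axis voxel spacing (defaults to isotropic 1).
#' @return numeric array of distances.
#' @export
distance_transform <- function(mask, spacing = NULL) {
  dispatch("ndimage.distance_transform_edt", mask, spacing = spacing)
}

.ref_edt <- function(x, spacing = NULL) {
  m <- as_mask(x)
  d <- dim(m)
  if (is.null(spacing)) spacing <- rep(1, length(d))
  array(sqrt(cpp_edt_sq(m, as.integer(d), as.double(spacing))), d)
}

#' Local maxima with a ball footprint
#'
#' A voxel is a maximum when no in-bounds voxel within the footprint exceeds
#' it; equal-valued plateaus are kept and can be merged into single markers by
#' labelling with the same footprint (see [watershed_markers()]).
#'
#' @param img image array.
#' @param radius footprint radius in voxels.
#' @return logical array.
#' @export
local_maxima <- function(img, radius) {
  dispatch("ndimage.local_maxima", img, radius = radius)
}

.ref_local_max <- function(x, radius, candidate = NULL) {
  d <- dim(x)
  off <- ball_offsets(radius, length(d))
  if (is.null(candidate)) candidate <- rep(TRUE, length(x))
  array(cpp_local_max(as.double(x), as.integer(d), off,
                      as.logical(candidate)), d)
}

#' Binary morphology with ball/disk structuring elements
#'
#' Out-of-image samples take the operation's identity value, so structures
#' touching the border are not clipped.
#'
#' @param mask logical array.
#' @param radius structuring element radius in voxels.
#' @return logical array.
#' @export
binary_erosion <- function(mask, radius) {
  dispatch("morphology.binary_erosion", mask, radius = radius)
}

#' @rdname binary_erosion
#' @export
binary_dilation <- function(mask, radius) {
  dispatch("morphology.binary_dilation", mask, radius = radius)
}

#' @rdname binary_erosion
#' @export
binary_closing <- function(mask, radius) {
  dispatch("morphology.binary_closing", mask, radius = radius)
}

.ref_morph <- function(x, radius, dilate) {
  m <- as_mask(x)
  d <- dim(m)
  off <- ball_offsets(radius, length(d))
  array(cpp_binary_morph(m, as.integer(d), off, dilate), d)
}

.ref_erosion <- function(x, radius) .ref_morph(x, radius, FALSE)
.ref_dilation <- function(x, radius) .ref_morph(x, radius, TRUE)
.ref_closing <- function(x, radius) .ref_morph(.ref_morph(x, radius, TRUE), radius, FALSE)

#' Seeded watershed
#'
#' Floods `relief` from the marker voxels upward (low values first) with face
#' connectivity, restricted to `mask`; FIFO tie-breaking makes the result
#' deterministic. When `markers` is `NULL`, markers are derived from plateaus
#' of local maxima of the Euclidean distance transform of `mask` detected with
#' a ball footprint of `footprint_radius` (maxima closer than the footprint
#' merge into one marker), and the relief defaults to the negated distance
#' transform.
#'
#' @param relief numeric array; watershed lines form on its crests.
#' @param markers integer label array of seeds, or `NULL` to derive from the
#'   distance transform of `mask`.
#' @param mask logical array restricting the flood.
#' @param footprint_radius ball radius for maxima detection (marker-free mode).
#' @return integer label array.
#' @export
watershed_segment <- function(relief = NULL, markers = NULL, mask,
                              footprint_radius = 3) {
  mask <- as_mask(vol_data(mask))
  if (is.null(markers)) {
    edt <- .ref_edt(mask)
    markers <- watershed_markers(edt, mask, footprint_radius)
    if (is.null(relief)) relief <- -edt
  }
  if (is.null(relief)) stop("relief required when markers are given",
                            call. = FALSE)
  dispatch("segmentation.watershed", relief, markers = markers, mask = mask)
}

#' @rdname watershed_segment
#' @param edt distance (or other height) map whose maxima seed the watershed.
#' @export
watershed_markers <- function(edt, mask, footprint_radius) {
  edt <- vol_data(edt)
  mask <- as_mask(mask)
  d <- dim(edt)
  off <- ball_offsets(footprint_radius, length(d))
  cand <- mask & edt > 0
  mx <- array(cpp_local_max(as.double(edt), as.integer(d), off,
                            as.logical(cand)), d)
  mx <- mx & cand
  # merge plateau maxima lying within one footprint into a single marker
  array(cpp_label(mx, as.integer(d), off), d)
}

.ref_watershed <- function(relief, markers, mask) {
  d <- dim(relief)
  array(cpp_watershed(as.double(relief), as.integer(vol_data(markers)),
                      as_mask(mask), as.integer(d)), d)
}

#' Fill small holes in a binary mask, slice by slice
#'
#' Background components of each 2-D (Y,X) slice that do not touch the slice
#' border and are smaller than `area_threshold` pixels are filled.
#'
#' @param mask logical array (2-D or 3-D).
#' @param area_threshold holes strictly smaller than this area are filled.
#' @return logical array.
#' @export
fill_holes <- function(mask, area_threshold) {
  mask <- as_mask(mask)
  d <- dim(mask)
  fill2d <- function(sl) {
    bg <- !sl
    lab <- .ref_label(bg, "face")
    if (max(lab) == 0L) return(sl)
    border <- unique(c(lab[1L, ], lab[nrow(lab), ], lab[, 1L], lab[, ncol(lab)]))
    sz <- tabulate(lab, nbins = max(lab))
    fill_ids <- setdiff(which(sz < area_threshold & sz > 0L), border)
    if (length(fill_ids)) sl[lab %in% fill_ids] <- TRUE
    sl
  }
  if (length(d) == 2L) return(fill2d(mask))
  for (z in seq_len(d[1L])) mask[z, , ] <- fill2d(mask[z, , ])
  mask
}

#' Drop labelled objects below a minimum size
#'
#' @param labels integer label array.
#' @param min_size objects with fewer voxels are removed (set to background).
#' @param relabel canonicalize surviving labels with [relabel_canonical()].
#' @return integer label array.
#' @export
size_filter <- function(labels, min_size, relabel = TRUE) {
  labels <- vol_data(labels)
  mx <- max(labels)
  if (mx > 0L) {
    sz <- tabulate(labels, nbins = mx)
    drop <- which(sz < min_size)
    if (length(drop)) labels[labels %in% drop] <- 0L
  }
  if (relabel) relabel_canonical(labels) else labels
}

#' Canonical relabelling of an instance segmentation
#'
#' Labels are renumbered 1..n by descending object size, ties broken by
#' lexicographic (Z,Y,X) centroid, making labelings comparable across runs and
#' backends.
#'
#' @param labels integer label array.
#' @return integer label array with consecutive labels starting at 1.
#' @export
relabel_canonical <- function(labels) {
  labels <- vol_data(labels)
  ids <- sort(unique(labels[labels > 0L]))
  if (!length(ids)) return(array(0L, dim(labels)))
  d <- dim(labels)
  sz <- tabulate(labels, nbins = max(ids))[ids]
  # centroids per axis
  cent <- sapply(seq_along(d), function(ax) {
    co <- slice.index(labels, ax)
    as.numeric(tapply(co[labels > 0L], labels[labels > 0L], mean))[
      match(ids, sort(unique(labels[labels > 0L])))]
  })
  if (is.null(dim(cent))) cent <- matrix(cent, nrow = 1L)
  ord <- do.call(order, c(list(-sz), as.data.frame(cent)))
  new <- integer(max(ids))
  new[ids[ord]] <- seq_along(ids)
  out <- labels
  out[labels > 0L] <- new[labels[labels > 0L]]
  array(as.integer(out), d)
}
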
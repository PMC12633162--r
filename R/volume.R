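#' Multi-dimensional image volume
#'
#' An `image_volume` is a dense numeric array with an axis convention drawn
#' from `C`, `Z`, `Y`, `X` and a backend residence tag. Spatial axes are
#' ordered `(Z,)Y,X`; a channel axis, when present, comes first. Most voxkit
#' functions accept plain arrays as well and coerce them with
#' [as_image_volume()].
#'
#' @param data numeric array or matrix (2-4 dimensions), all elements finite.
#' @param axes character vector of axis labels, one per array dimension,
#'   e.g. `c("Z","Y","X")`. Inferred from the rank when `NULL`
#'   (2 -> YX, 3 -> ZYX, 4 -> CZYX).
#' @param residence backend holding the data, `"reference"` or
#'   `"accelerated"`.
#' @return an object of class `image_volume`.
#' @examples
#' v <- image_volume(array(runif(2 * 4 * 4), c(2, 4, 4)))
#' axes(v)
#' @export
image_volume <- function(data, axes = NULL, residence = "reference") {
  if (is.matrix(data)) data <- array(data, dim(data))
  if (!is.array(data) || !is.numeric(data))
    stop("`data` must be a numeric array", call. = FALSE)
  nd <- length(dim(data))
  if (nd < 2L || nd > 4L)
    stop("image_volume supports 2-4 dimensions, got rank ", nd, call. = FALSE)
  if (is.null(axes)) axes <- infer_axes(nd)
  axes <- toupper(as.character(axes))
  if (length(axes) != nd || !all(axes %in% c("C", "Z", "Y", "X")) ||
      anyDuplicated(axes))
    stop("invalid axis labels: ", paste(axes, collapse = ","), call. = FALSE)
  sp <- setdiff(axes, "C")
  if (!identical(sp, intersect(c("Z", "Y", "X"), sp)) ||
      length(sp) < 2L || ("C" %in% axes && axes[1L] != "C"))
    stop("axes must be (C)(Z)YX ordered", call. = FALSE)
  if (!all(is.finite(data)))
    stop("image data must be finite", call. = FALSE)
  residence <- match.arg(residence, c("reference", "accelerated"))
  structure(list(data = data, axes = axes, residence = residence),
            class = "image_volume")
}

infer_axes <- function(nd) {
  switch(nd, NULL, c("Y", "X"), c("Z", "Y", "X"), c("C", "Z", "Y", "X"))
}

#' @rdname image_volume
#' @param x object to coerce / query.
#' @export
as_image_volume <- function(x, axes = NULL, residence = "reference") {
  if (is_image_volume(x)) return(x)
  image_volume(x, axes = axes, residence = residence)
}

#' @rdname image_volume
#' @export
is_image_volume <- function(x) inherits(x, "image_volume")

#' @rdname image_volume
#' @export
axes <- function(x) {
  if (is_image_volume(x)) x$axes else infer_axes(length(dim(x)))
}

#' @rdname image_volume
#' @export
residence <- function(x) if (is_image_volume(x)) x$residence else "reference"

#' Extract the raw array from an image volume
#'
#' @param x an `image_volume` or array.
#' @return the underlying numeric array (host copy).
#' @export
vol_data <- function(x) if (is_image_volume(x)) x$data else x

#' @export
dim.image_volume <- function(x) dim(x$data)

#' @export
as.array.image_volume <- function(x, ...) x$data

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume> %s [%s] on %s backend\n",
              paste(dim(x$data), collapse = "x"),
              paste(x$axes, collapse = ""), x$residence))
  rng <- range(x$data)
  cat(sprintf("  range [%.4g, %.4g]\n", rng[1L], rng[2L]))
  invisible(x)
}

# rebuild a volume around new data, keeping metadata of a template
rewrap <- function(data, template) {
  if (is_image_volume(template)) {
    ax <- if (length(dim(data)) == length(template$axes)) template$axes else NULL
    image_volume(data, axes = ax, residence = template$residence)
  } else {
    data
  }
}

# run fn on the raw array(s), returning the same container kind as `x`
with_data <- function(x, fn) rewrap(fn(vol_data(x)), x)
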
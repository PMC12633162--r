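## TIFF input/output, configuration and provenance -------------------------
##
## Images are stored as multi-page TIFF (one YX page per leading-axis index)
## plus a JSON sidecar (<path>.json) carrying axes, shape, storage kind and
## the affine intensity scaling used for float data. Float images are written
## as 32-bit float after rescaling to [0, 1] (the writer's supported range);
## the sidecar restores the original range on read, so the round trip is
## exact at float32 precision. Label volumes are written as 16-bit unsigned
## when the maximum label fits, else as 32-bit unsigned via a minimal raw
## writer (readable by standard TIFF readers).

sidecar_path <- function(path) paste0(path, ".json")

#' Write an image or label volume to TIFF
#'
#' @param img numeric array, integer label array, or `image_volume`
#'   (device-resident volumes are transferred to host automatically).
#' @param path output TIFF path; a JSON sidecar `<path>.json` with axes,
#'   shape and scaling is written beside it.
#' @param labels write as an unsigned-integer label volume (16-bit when the
#'   maximum label fits, else 32-bit).
#' @return invisibly, a list describing the volume on disk (path, axes,
#'   dtype, shape).
#' @export
write_volume <- function(img, path, labels = FALSE) {
  if (is_image_volume(img) && img$residence != "reference") img <- to_host(img)
  ax <- axes(img)
  x <- vol_data(img)
  d <- dim(x)
  nd <- length(d)
  if (nd < 2L || nd > 4L)
    stop("write_volume supports rank 2-4", call. = FALSE)
  pages <- split_pages(x)
  meta <- list(axes = paste(ax, collapse = ""), shape = d,
               writer = "voxkit", version = as.character(pkg_version()))
  if (labels) {
    if (any(x < 0) || any(x != round(x)))
      stop("label volumes must contain non-negative integers", call. = FALSE)
    mx <- max(x)
    if (mx <= 65535) {
      meta$dtype <- "uint16"
      tiff::writeTIFF(lapply(pages, function(p) p / 65535),
                      path, bits.per.sample = 16L)
    } else {
      meta$dtype <- "uint32"
      write_tiff_u32(pages, path)
    }
  } else {
    lo <- min(x); hi <- max(x)
    scale <- if (hi > lo) hi - lo else 1
    meta$dtype <- "float32"
    meta$offset <- lo
    meta$scale <- scale
    tiff::writeTIFF(lapply(pages, function(p) (p - lo) / scale),
                    path, bits.per.sample = 32L)
  }
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(list(path = path, axes = ax, dtype = meta$dtype, shape = d))
}

split_pages <- function(x) {
  d <- dim(x)
  nd <- length(d)
  if (nd == 2L) return(list(x))
  lead <- prod(d[seq_len(nd - 2L)])
  m <- matrix(aperm(x, c(nd - 1L, nd, seq_len(nd - 2L))), nrow = d[nd - 1L])
  lapply(seq_len(lead), function(i)
    matrix(m[, ((i - 1L) * d[nd]  + 1L):(i * d[nd])], d[nd - 1L], d[nd]))
}

join_pages <- function(pages, d) {
  nd <- length(d)
  if (nd == 2L) return(array(pages[[1L]], d))
  flat <- array(unlist(pages, use.names = FALSE), c(d[nd - 1L], d[nd],
                                                    d[seq_len(nd - 2L)]))
  aperm(flat, c(2L + seq_len(nd - 2L), 1L, 2L))
}

#' Read a volume written by [write_volume()] (or any plain TIFF)
#'
#' Axes come from the JSON sidecar when present; otherwise they are inferred
#' from the rank (2 -> YX, 3 -> ZYX stacking the pages along Z, 4 -> CZYX)
#' and the assumption is recorded in the dispatch log. Residence is always
#' `reference`.
#'
#' @param path TIFF path.
#' @return an `image_volume` (intensities) or integer array (label dtypes).
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("cannot read ", path, call. = FALSE)
  meta <- NULL
  if (file.exists(sidecar_path(path)))
    meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  # as.is keeps integer samples unscaled but must be off for float storage
  if (!is.null(meta)) {
    as_is <- !identical(meta$dtype, "float32")
  } else {
    probe <- tiff::readTIFF(path, info = TRUE)
    fmt <- attr(probe, "sample.format")
    bits <- attr(probe, "bits.per.sample")
    # 32-bit samples without an explicit unsigned tag are float storage
    as_is <- !(identical(bits, 32L) && !identical(fmt, "uint"))
  }
  pages <- tiff::readTIFF(path, all = TRUE, as.is = as_is)
  if (!is.list(pages)) pages <- list(pages)
  if (any(vapply(pages, function(p) length(dim(p)), 0L) > 2L))
    stop("unsupported layout: TIFF pages with extra sample dimensions",
         call. = FALSE)
  if (!is.null(meta)) {
    d <- as.integer(meta$shape)
    if (length(d) > 4L) stop("unsupported layout: rank > 4", call. = FALSE)
    x <- join_pages(pages, d)
    if (identical(meta$dtype, "float32"))
      x <- x * meta$scale + meta$offset
    if (identical(meta$dtype, "uint16") || identical(meta$dtype, "uint32")) {
      if (identical(meta$dtype, "uint16") && max(x) <= 1)
        x <- round(x * 65535)
      return(array(as.integer(round(x)), d))
    }
    return(image_volume(x, axes = strsplit(meta$axes, "")[[1L]]))
  }
  vx_log("assumption", op = "read_volume",
         direction = paste0("axes inferred for rank ",
                            if (length(pages) > 1L) 3L else 2L))
  d2 <- dim(pages[[1L]])
  if (length(pages) == 1L) return(image_volume(array(pages[[1L]], d2)))
  image_volume(join_pages(pages, c(length(pages), d2)))
}

pkg_version <- function() {
  tryCatch(utils::packageVersion("voxkit"), error = function(e) "0.0.0")
}

## minimal raw uint32 TIFF writer (little-endian, one strip per page) -------

write_tiff_u32 <- function(pages, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  u16 <- function(v) writeBin(as.integer(v), con, size = 2, endian = "little")
  u32 <- function(v) writeBin(as.integer(v), con, size = 4, endian = "little")
  # header
  writeBin(charToRaw("II"), con); u16(42L)
  n <- length(pages)
  h <- nrow(pages[[1L]]); w <- ncol(pages[[1L]])
  strip_bytes <- as.numeric(w) * h * 4
  # layout: header(8) + per page [pixel strip][IFD]
  n_entries <- 8L
  ifd_size <- 2 + n_entries * 12 + 4
  offs <- 8
  strip_off <- integer(n); ifd_off <- integer(n)
  for (i in seq_len(n)) {
    strip_off[i] <- offs
    ifd_off[i] <- offs + strip_bytes
    offs <- offs + strip_bytes + ifd_size
  }
  u32(ifd_off[1L])
  entry <- function(tag, type, count, value) {
    u16(tag); u16(type); u32(count); u32(value)
  }
  for (i in seq_len(n)) {
    # pixel data, row-major uint32 (split into two uint16 halves to avoid
    # R's signed 32-bit limits)
    v <- as.numeric(t(pages[[i]]))
    lo <- v %% 65536
    hi <- v %/% 65536
    inter <- as.integer(rbind(lo, hi))  # little-endian 16-bit pairs
    writeBin(inter, con, size = 2, endian = "little")
    u16(n_entries)
    entry(256L, 3L, 1L, w)              # ImageWidth
    entry(257L, 3L, 1L, h)              # ImageLength
    entry(258L, 3L, 1L, 32L)            # BitsPerSample
    entry(262L, 3L, 1L, 1L)             # Photometric: BlackIsZero
    entry(273L, 4L, 1L, strip_off[i])   # StripOffsets
    entry(278L, 3L, 1L, h)              # RowsPerStrip
    entry(279L, 4L, 1L, strip_bytes)    # StripByteCounts
    entry(339L, 3L, 1L, 1L)             # SampleFormat: unsigned int
    u32(if (i < n) ifd_off[i + 1L] else 0L)
  }
  invisible(path)
}

## configuration ------------------------------------------------------------

#' Read / write a monolayer pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @return [read_config()]: a [monolayer_config()].
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(monolayer_config, vals)
}

#' @rdname read_config
#' @param cfg a [monolayer_config()].
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "monolayer_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

## provenance ---------------------------------------------------------------

# polynomial rolling hash of a serialized object, as hex
config_hash <- function(obj) {
  raw <- serialize(obj, NULL, version = 2L)
  h <- 0
  for (b in as.integer(raw)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Write a provenance sidecar next to pipeline outputs
#'
#' Records package version, a hash of the configuration/parameters, the seed
#' and the backend used, so every run is attributable.
#'
#' @param path output JSON path.
#' @param params list of parameters / configuration.
#' @param seed integer seed used.
#' @param backend backend name.
#' @return invisibly, the provenance record.
#' @export
write_provenance <- function(path, params = list(), seed = NA_integer_,
                             backend = "reference") {
  rec <- list(tool = "voxkit", version = as.character(pkg_version()),
              time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
              config_hash = config_hash(params), seed = seed,
              backend = backend)
  jsonlite::write_json(rec, path, auto_unbox = TRUE)
  invisible(rec)
}
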
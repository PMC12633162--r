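## Backend registry and dispatch -------------------------------------------
##
## Every mirrored operation is registered per backend in `.vx`. The reference
## (host) backend is always present; an accelerated backend can be plugged in
## with register_backend() and is reported by probe_backends() only when its
## availability probe succeeds. Dispatch routes each call to the backend on
## which the primary array argument resides, transparently falling back to the
## reference implementation (with host round-trip) when the accelerated
## backend lacks the operation.

.vx <- new.env(parent = emptyenv())

init_backend_state <- function() {
  .vx$backends <- list(
    reference = list(
      available = function() TRUE,
      transfer_in = identity,
      transfer_out = identity,
      ops = new.env(parent = emptyenv())
    )
  )
  .vx$log <- list()
}

#' Register or remove a compute backend
#'
#' The reference backend is built in and cannot be replaced. An accelerated
#' backend supplies an availability probe plus transfer functions mapping host
#' arrays to device arrays and back; operations are then attached with
#' [register_op()]. Absent or failing backends never raise: they simply do not
#' appear in [probe_backends()].
#'
#' @param name backend name (currently only `"accelerated"` is meaningful).
#' @param available function() returning TRUE when the runtime and a device
#'   are usable; any error counts as unavailable.
#' @param transfer_in,transfer_out functions converting a host array to the
#'   backend's representation and back.
#' @return invisibly, the backend name.
#' @export
register_backend <- function(name, available,
                             transfer_in = identity,
                             transfer_out = identity) {
  stopifnot(is.character(name), length(name) == 1L)
  if (name == "reference")
    stop("the reference backend is built in", call. = FALSE)
  .vx$backends[[name]] <- list(
    available = available, transfer_in = transfer_in,
    transfer_out = transfer_out, ops = new.env(parent = emptyenv())
  )
  invisible(name)
}

#' @rdname register_backend
#' @export
unregister_backend <- function(name) {
  if (name == "reference")
    stop("the reference backend is built in", call. = FALSE)
  .vx$backends[[name]] <- NULL
  invisible(name)
}

#' Attach an operation implementation to a backend
#'
#' @param op_name qualified operation name, e.g. `"filters.gaussian"`.
#' @param fn implementation; receives raw arrays (in the backend's
#'   representation) plus the remaining arguments.
#' @param backend backend name.
#' @export
register_op <- function(op_name, fn, backend = "reference") {
  be <- .vx$backends[[backend]]
  if (is.null(be)) stop("unknown backend: ", backend, call. = FALSE)
  assign(op_name, fn, envir = be$ops)
  invisible(op_name)
}

#' List operations mirrored by a backend
#' @param backend backend name.
#' @export
backend_ops <- function(backend = "reference") {
  be <- .vx$backends[[backend]]
  if (is.null(be)) return(character())
  sort(ls(be$ops))
}

accelerated_available <- function() {
  if (nzchar(Sys.getenv("VOXKIT_FORCE_REFERENCE", ""))) return(FALSE)
  be <- .vx$backends[["accelerated"]]
  if (is.null(be)) return(FALSE)
  ok <- tryCatch(isTRUE(be$available()), error = function(e) FALSE)
  ok
}

#' Probe which compute backends are usable
#'
#' Always contains `"reference"`; contains `"accelerated"` only when an
#' accelerated backend is registered and its runtime probe succeeds. Probing
#' never raises; failures degrade to reference-only. The environment variable
#' `VOXKIT_FORCE_REFERENCE` forces reference-only mode.
#'
#' @return character vector of backend names.
#' @export
probe_backends <- function() {
  out <- "reference"
  if (accelerated_available()) out <- c(out, "accelerated")
  out
}

vx_log <- function(event, op = NA_character_, direction = NA_character_,
                   shape = NULL, level = "info") {
  rec <- list(event = event, op = op, direction = direction,
              shape = shape, level = level, time = Sys.time())
  .vx$log[[length(.vx$log) + 1L]] <- rec
  invisible(rec)
}

#' Inspect or clear the structured dispatch log
#'
#' Every implicit transfer, fallback and degraded-mode event is recorded
#' (operation, direction, array shape) because implicit transfers are a
#' performance trap worth observing.
#' @return list of log records.
#' @export
dispatch_log <- function() .vx$log

#' @rdname dispatch_log
#' @export
clear_dispatch_log <- function() { .vx$log <- list(); invisible(NULL) }

#' Move an image volume to the accelerated device (or keep it on host)
#'
#' When no accelerated backend is usable the input is returned unchanged with
#' reference residence and a warning-level log record; this never errors, so
#' pipelines run unmodified on host-only machines.
#'
#' @param img an `image_volume` or array.
#' @return an `image_volume`; values identical, residence updated.
#' @export
to_device <- function(img) {
  img <- as_image_volume(img)
  if (!accelerated_available()) {
    if (img$residence != "reference") img$residence <- "reference"
    vx_log("degraded", direction = "to_device", shape = dim(img),
           level = "warning")
    return(img)
  }
  if (img$residence == "accelerated") return(img)
  be <- .vx$backends[["accelerated"]]
  img$data <- be$transfer_in(img$data)
  img$residence <- "accelerated"
  vx_log("transfer", direction = "host->device", shape = dim(img))
  img
}

#' Move an image volume back to the host
#' @param img an `image_volume` or array.
#' @return an `image_volume` with reference residence and identical values.
#' @export
to_host <- function(img) {
  img <- as_image_volume(img)
  if (img$residence == "reference") return(img)
  be <- .vx$backends[["accelerated"]]
  if (!is.null(be)) img$data <- be$transfer_out(img$data)
  img$residence <- "reference"
  vx_log("transfer", direction = "device->host", shape = dim(img))
  img
}

is_arraylike <- function(x) is_image_volume(x) || (is.array(x) && is.numeric(x)) ||
  (is.array(x) && is.logical(x))

#' Dispatch a mirrored operation to the backend of its primary argument
#'
#' The first array-typed argument decides the backend ("primary-argument
#' rule"); secondary arrays on a different residence are transferred
#' automatically and logged. When the accelerated backend lacks the named
#' operation the call falls back to the reference implementation via a host
#' round-trip (logged), never raising. With reference residence the result is
#' bit-identical to calling the reference implementation directly.
#'
#' @param op_name qualified operation name (see [backend_ops()]).
#' @param ... operation arguments; `image_volume`s are unwrapped to raw
#'   arrays for the implementation and results are re-wrapped on the primary
#'   argument's residence.
#' @return the operation's result; array results carry the primary argument's
#'   residence.
#' @export
dispatch <- function(op_name, ...) {
  args <- list(...)
  prim <- Position(is_arraylike, args)
  if (is.na(prim) || is.null(prim))
    stop("dispatch: no array argument found for ", op_name, call. = FALSE)
  target <- residence(args[[prim]])
  if (target == "accelerated" && !accelerated_available()) target <- "reference"
  be <- .vx$backends[[target]]
  fn <- get0(op_name, envir = be$ops, inherits = FALSE)
  used <- target
  if (is.null(fn) && target == "accelerated") {
    # accelerated backend lacks the op: host round-trip fallback
    vx_log("fallback", op = op_name, direction = "device->host->device",
           shape = dim(vol_data(args[[prim]])))
    used <- "reference"
    fn <- get0(op_name, envir = .vx$backends$reference$ops, inherits = FALSE)
  }
  if (is.null(fn))
    stop("unsupported operation '", op_name,
         "' in voxkit mirrored namespace (searched backend: ", target, ")",
         call. = FALSE)
  raw_args <- lapply(seq_along(args), function(i) {
    a <- args[[i]]
    if (!is_arraylike(a)) return(a)
    res <- residence(a)
    if (res != used && is_image_volume(a)) {
      vx_log("transfer", op = op_name,
             direction = paste0(res, "->", used), shape = dim(a))
    }
    x <- vol_data(a)
    if (used == "accelerated" && res == "reference")
      x <- .vx$backends$accelerated$transfer_in(x)
    if (used == "reference" && res == "accelerated")
      x <- .vx$backends$accelerated$transfer_out(x)
    x
  })
  out <- do.call(fn, raw_args)
  finish <- function(x) {
    if (!is_arraylike(x)) return(x)
    if (target == "accelerated" && used == "reference")
      x <- .vx$backends$accelerated$transfer_in(x)
    if (is_image_volume(args[[prim]]) && is.numeric(x) &&
        length(dim(x)) >= 2L && length(dim(x)) <= 4L)
      image_volume(strip_tags(x), axes = keep_axes(args[[prim]], x),
                   residence = target)
    else x
  }
  if (is_arraylike(out)) finish(out)
  else if (is.list(out)) lapply(out, finish)
  else out
}

# helper: drop backend tags a mock transfer may attach before validation
strip_tags <- function(x) {
  attributes(x) <- attributes(x)[c("dim")]
  x
}

keep_axes <- function(template, x) {
  if (length(dim(x)) == length(axes(template))) axes(template) else NULL
}
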
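#' FLIP image stacks
#'
#' The universal currency of the package: a 3-D array of non-negative
#' intensities `I(row, col, frame)` plus the frame interval `dt` in seconds
#' (one frame per bleach/acquire cycle; frames assumed uniformly spaced, so
#' frame `n` corresponds to `t = (n - 1) * dt`).
#'
#' @param data numeric 3-D array `height x width x frames` (a matrix is
#'   accepted as a single frame).
#' @param dt frame interval in seconds (> 0).
#' @return An object of class `flip_stack`: a list with elements `data`
#'   and `dt`.
#' @export
flip_stack <- function(data, dt) {
  if (is.matrix(data)) data <- array(data, c(dim(data), 1L))
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("'data' must be a height x width x frames array", call. = FALSE)
  if (!is.numeric(dt) || length(dt) != 1L || is.na(dt) || dt <= 0)
    stop("'dt' must be a single positive number of seconds", call. = FALSE)
  storage.mode(data) <- "double"
  structure(list(data = data, dt = dt), class = "flip_stack")
}

#' @export
print.flip_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("FLIP image stack: %d x %d px, %d frames, dt = %g s\n",
              d[1], d[2], d[3], x$dt))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.flip_stack <- function(x) dim(x$data)

#' Number of frames in a stack
#' @param stack a [flip_stack()].
#' @return Integer frame count.
#' @export
n_frames <- function(stack) dim(stack$data)[3]

#' Extract one frame as a matrix
#' @param stack a [flip_stack()].
#' @param n frame number (1-based).
#' @return `height x width` numeric matrix.
#' @export
get_frame <- function(stack, n) {
  k <- n_frames(stack)
  if (n < 1 || n > k) stop("frame index out of range", call. = FALSE)
  stack$data[, , n]
}

check_stack <- function(stack, arg = "stack") {
  if (!inherits(stack, "flip_stack"))
    stop(sprintf("'%s' must be a flip_stack", arg), call. = FALSE)
  stack
}

sidecar_path <- function(path) paste0(sub("\\.tiff?$", "", path), ".json")

#' Read a FLIP stack from a multi-page TIFF
#'
#' Pages are taken in time order; intensities are returned as floats without
#' rescaling for 8/16-bit integer TIFFs. 32-bit pages are treated as float
#' samples. A sidecar JSON written by [write_stack()] (same path with a
#' `.json` extension) supplies `dt` and any storage scale; TIFF metadata is
#' never trusted for timing, so without a sidecar `dt` must be given
#' explicitly.
#'
#' @param path TIFF file path.
#' @param dt frame interval in seconds; required when no sidecar JSON is
#'   present (overrides the sidecar when given).
#' @param min_frames minimum accepted frame count (the DMD pipeline needs at
#'   least 3 frames downstream).
#' @return A [flip_stack()].
#' @export
read_stack <- function(path, dt = NULL, min_frames = 3L) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (length(pages) < min_frames)
    stop(sprintf("stack has %d frame(s); at least %d are required",
                 length(pages), min_frames), call. = FALSE)
  bits <- attr(pages[[1]], "bits.per.sample")
  if (!identical(as.integer(bits), 32L))  # integer samples: unscaled counts
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (length(dim(pages[[1]])) > 2L)
    stop("multi-channel/RGB TIFF: extract a single channel first",
         call. = FALSE)
  scale <- 1; offset <- 0
  side <- sidecar_path(path)
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    if (is.null(dt)) dt <- meta$dt
    if (!is.null(meta$scale)) scale <- meta$scale
    if (!is.null(meta$offset)) offset <- meta$offset
  }
  if (is.null(dt))
    stop("frame interval 'dt' not given and no sidecar JSON found",
         call. = FALSE)
  arr <- simplify2array(lapply(pages, as.vector))
  arr <- array(arr * scale + offset,
               c(dim(pages[[1]]), length(pages)))
  flip_stack(arr, dt)
}

#' Write a FLIP stack as a 32-bit float multi-page TIFF plus sidecar JSON
#'
#' Float TIFF samples are stored in `[0, 1]`; intensities are affinely
#' rescaled to that range before writing and the scale and offset recorded,
#' together with `dt` and the stack dimensions, in a sidecar JSON next to
#' the TIFF. The
#' write/read round trip preserves values to float32 precision.
#'
#' @param stack a [flip_stack()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  check_stack(stack)
  k <- n_frames(stack)
  lo <- min(stack$data); hi <- max(stack$data)
  span <- if (hi > lo) hi - lo else 1
  pages <- lapply(seq_len(k), function(n) (stack$data[, , n] - lo) / span)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  meta <- list(dt = stack$dt, scale = span, offset = lo,
               height = dim(stack)[1], width = dim(stack)[2], frames = k)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
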
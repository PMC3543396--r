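#' FrameStack: the universal time-lapse video container
#'
#' A `frame_stack` holds `T` ordered frames of `H x W` pixels with `C`
#' channels of 8-bit intensities (stored as base-R doubles in `[0, 255]`),
#' together with channel labels and the *origin index* of every frame, i.e.
#' its 0-based position in the original acquisition. Origin indices survive
#' frame removal, which is what keeps timestamps accurate after gating.
#'
#' @param frames numeric array of dimension `c(H, W, C, T)` with values in
#'   `[0, 255]`. A `H x W x T` array or `H x W` matrix is promoted to `C = 1`
#'   (and `T = 1` for a matrix).
#' @param channel_names character vector of `C` labels. Defaults to
#'   `"gray"` for `C = 1` and `c("red", "green", "blue")` for `C = 3`.
#' @param origin_indices integer vector of `T` strictly increasing 0-based
#'   original frame numbers. Defaults to `0:(T-1)`.
#'
#' @return An object of class `frame_stack`.
#' @export
frame_stack <- function(frames, channel_names = NULL, origin_indices = NULL) {
  if (is.matrix(frames)) dim(frames) <- c(dim(frames), 1L, 1L)
  if (length(dim(frames)) == 3L) {
    d <- dim(frames)
    dim(frames) <- c(d[1L], d[2L], 1L, d[3L])
  }
  if (length(dim(frames)) != 4L)
    stop("'frames' must be an H x W x C x T array")
  d <- dim(frames)
  if (!d[3L] %in% c(1L, 3L))
    stop("channel count must be 1 or 3, got ", d[3L])
  if (anyNA(frames) || min(frames) < 0 || max(frames) > 255)
    stop("intensities must lie in [0, 255] with no missing values")
  storage.mode(frames) <- "double"
  if (is.null(channel_names))
    channel_names <- if (d[3L] == 1L) "gray" else c("red", "green", "blue")
  if (length(channel_names) != d[3L])
    stop("need exactly ", d[3L], " channel names")
  if (is.null(origin_indices)) origin_indices <- seq_len(d[4L]) - 1L
  origin_indices <- as.integer(origin_indices)
  if (length(origin_indices) != d[4L])
    stop("origin_indices must have one entry per frame")
  if (d[4L] > 1L && any(diff(origin_indices) <= 0L))
    stop("origin_indices must be strictly increasing")
  structure(
    list(frames = frames, channel_names = as.character(channel_names),
         origin_indices = origin_indices),
    class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<frame_stack> %d frame(s), %d x %d px, %d channel(s) [%s]\n",
              d[4L], d[1L], d[2L], d[3L],
              paste(x$channel_names, collapse = ", ")))
  cat(sprintf("  origin indices %d..%d, intensity range [%g, %g]\n",
              x$origin_indices[1L], x$origin_indices[d[4L]],
              min(x$frames), max(x$frames)))
  invisible(x)
}

#' Number of frames in a stack
#' @param stack a `frame_stack`.
#' @return integer frame count `T`.
#' @export
n_frames <- function(stack) {
  stopifnot(inherits(stack, "frame_stack"))
  dim(stack$frames)[4L]
}

#' Stack dimensions
#' @param stack a `frame_stack`.
#' @return named integer vector `c(H, W, C, T)`.
#' @export
stack_dim <- function(stack) {
  stopifnot(inherits(stack, "frame_stack"))
  d <- dim(stack$frames)
  names(d) <- c("H", "W", "C", "T")
  d
}

#' Extract one frame as an H x W x C array
#' @param stack a `frame_stack`.
#' @param t 1-based positional frame index.
#' @return numeric `H x W x C` array.
#' @export
get_frame <- function(stack, t) {
  stopifnot(inherits(stack, "frame_stack"))
  d <- dim(stack$frames)
  if (t < 1L || t > d[4L]) stop("frame index out of range")
  array(stack$frames[, , , t], dim = d[1:3])
}

#' Extract a named channel as an H x W x T array
#' @param stack a `frame_stack`.
#' @param channel channel label, one of `stack$channel_names`.
#' @return numeric `H x W x T` array.
#' @export
get_channel <- function(stack, channel) {
  stopifnot(inherits(stack, "frame_stack"))
  ci <- match(channel, stack$channel_names)
  if (is.na(ci))
    stop("unknown channel '", channel, "'; available: ",
         paste(stack$channel_names, collapse = ", "))
  d <- dim(stack$frames)
  array(stack$frames[, , ci, ], dim = d[c(1L, 2L, 4L)])
}

#' Subset frames by position, preserving origin indices
#' @param stack a `frame_stack`.
#' @param positions 1-based positional indices, strictly increasing.
#' @return a new `frame_stack` with the selected frames.
#' @export
subset_frames <- function(stack, positions) {
  stopifnot(inherits(stack, "frame_stack"))
  positions <- as.integer(positions)
  d <- dim(stack$frames)
  if (length(positions) == 0L) stop("a frame_stack cannot be empty")
  if (any(positions < 1L) || any(positions > d[4L]))
    stop("frame positions out of range")
  frame_stack(stack$frames[, , , positions, drop = FALSE],
              channel_names = stack$channel_names,
              origin_indices = stack$origin_indices[positions])
}

# clamp to [0,255] and round half away from zero to the nearest 8-bit level
clamp8 <- function(x) pmin(pmax(floor(x + 0.5), 0), 255)
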
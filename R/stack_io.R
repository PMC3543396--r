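#' Read a time-lapse image stack
#'
#' Loads a multipage TIFF (8-bit grayscale or 24-bit RGB, one page per
#' frame), or a directory of numbered single-page TIFF/PNG files, into a
#' [frame_stack()]. If a JSON sidecar `<stem>.frames.json` written by
#' [write_stack()] sits next to the file, origin indices and channel names
#' are restored from it; otherwise origin indices default to `0..T-1`.
#'
#' @param path path to a multipage TIFF file or to a directory of
#'   single-page image files (sorted by file name).
#' @param layout `"rgb"` (pages carry 3 channels in red, green, blue order)
#'   or `"gray"` (single channel). Must match the file contents.
#' @return a `frame_stack`.
#' @export
read_stack <- function(path, layout = c("rgb", "gray")) {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop("cannot read '", path, "': no such file")
  pages <- if (dir.exists(path)) read_pages_dir(path) else read_pages_tiff(path)
  if (length(pages) == 0L) stop("no frames found in '", path, "'")

  pages <- lapply(pages, function(p) {
    if (is.matrix(p)) dim(p) <- c(dim(p), 1L)
    if (dim(p)[3L] == 4L) p <- p[, , 1:3, drop = FALSE]  # drop alpha
    p
  })
  dims <- vapply(pages, dim, integer(3))
  if (any(dims[1L, ] != dims[1L, 1L]) || any(dims[2L, ] != dims[2L, 1L]) ||
      any(dims[3L, ] != dims[3L, 1L]))
    stop("mixed frame dimensions across pages")
  C <- dims[3L, 1L]
  if (layout == "rgb" && C != 3L)
    stop("layout 'rgb' requested but pages have ", C, " channel(s)")
  if (layout == "gray" && C != 1L)
    stop("layout 'gray' requested but pages have ", C, " channel(s)")

  frames <- array(0, dim = c(dims[1L, 1L], dims[2L, 1L], C, length(pages)))
  for (t in seq_along(pages)) frames[, , , t] <- round(pages[[t]] * 255)

  sidecar <- sidecar_path(path)
  channel_names <- NULL
  origin_indices <- NULL
  if (!dir.exists(path) && file.exists(sidecar)) {
    sc <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(sc$origin_indices) &&
        length(sc$origin_indices) == length(pages))
      origin_indices <- sc$origin_indices
    if (!is.null(sc$channel_names) && length(sc$channel_names) == C)
      channel_names <- sc$channel_names
  }
  frame_stack(frames, channel_names = channel_names,
              origin_indices = origin_indices)
}

read_pages_tiff <- function(path) {
  pages <- tryCatch(
    tiff::readTIFF(path, all = TRUE, info = TRUE),
    error = function(e) stop("cannot read '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  for (p in pages) {
    bps <- attr(p, "bits.per.sample")
    if (!is.null(bps) && any(bps > 8L))
      stop("unsupported bit depth ", max(bps),
           " bits per sample; only 8-bit stacks are supported")
  }
  pages
}

read_pages_dir <- function(path) {
  files <- sort(list.files(path, pattern = "\\.(tif|tiff|png)$",
                           ignore.case = TRUE, full.names = TRUE))
  if (length(files) == 0L)
    stop("no TIFF/PNG files found in directory '", path, "'")
  lapply(files, function(f) {
    if (grepl("\\.png$", f, ignore.case = TRUE)) png::readPNG(f)
    else read_pages_tiff(f)[[1L]]
  })
}

sidecar_path <- function(path) {
  file.path(dirname(path),
            paste0(tools::file_path_sans_ext(basename(path)), ".frames.json"))
}

#' Write a stack as a multipage TIFF with a JSON sidecar
#'
#' One TIFF page per frame; 3-channel stacks are re-packed as 24-bit RGB.
#' A sidecar `<stem>.frames.json` records origin indices and channel names
#' so a write/read round trip preserves the full container, not just the
#' pixels.
#'
#' @param stack a `frame_stack`.
#' @param path destination file path; the parent directory must exist.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "frame_stack"))
  if (!dir.exists(dirname(path)))
    stop("parent directory '", dirname(path), "' does not exist")
  d <- dim(stack$frames)
  pages <- lapply(seq_len(d[4L]), function(t) {
    p <- stack$frames[, , , t]
    if (d[3L] == 1L) matrix(p, d[1L], d[2L]) / 255
    else array(p, dim = d[1:3]) / 255
  })
  ok <- tryCatch(
    tiff::writeTIFF(pages, path, bits.per.sample = 8L),
    error = function(e) stop("cannot write '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  jsonlite::write_json(
    list(origin_indices = stack$origin_indices,
         channel_names = stack$channel_names),
    sidecar_path(path), auto_unbox = FALSE)
  invisible(path)
}

#' Split an RGB stack into three single-channel stacks
#'
#' @param stack a 3-channel `frame_stack`.
#' @return named list of three single-channel `frame_stack`s (`red`,
#'   `green`, `blue` slots named after `stack$channel_names`), sharing the
#'   input's origin indices.
#' @export
split_channels <- function(stack) {
  stopifnot(inherits(stack, "frame_stack"))
  d <- dim(stack$frames)
  if (d[3L] != 3L) stop("split_channels requires a 3-channel stack")
  out <- lapply(1:3, function(ci)
    frame_stack(array(stack$frames[, , ci, ], dim = d[c(1L, 2L, 4L)]),
                channel_names = stack$channel_names[ci],
                origin_indices = stack$origin_indices))
  names(out) <- stack$channel_names
  out
}

#' Merge three single-channel stacks into one RGB stack
#'
#' Inverse of [split_channels()]: channels are packed in the order given
#' (red, green, blue).
#'
#' @param r,g,b single-channel `frame_stack`s with identical `T`, `H`, `W`
#'   and origin indices.
#' @return a 3-channel `frame_stack`.
#' @export
merge_channels <- function(r, g, b) {
  stacks <- list(r, g, b)
  for (s in stacks) {
    stopifnot(inherits(s, "frame_stack"))
    if (dim(s$frames)[3L] != 1L)
      stop("merge_channels requires single-channel stacks")
  }
  d <- dim(r$frames)
  for (s in stacks[2:3]) {
    if (!identical(dim(s$frames), d))
      stop("all three stacks must share dimensions")
    if (!identical(s$origin_indices, r$origin_indices))
      stop("all three stacks must share origin indices")
  }
  frames <- array(0, dim = c(d[1L], d[2L], 3L, d[4L]))
  for (ci in 1:3) frames[, , ci, ] <- stacks[[ci]]$frames[, , 1L, ]
  frame_stack(frames,
              channel_names = vapply(stacks, function(s)
                s$channel_names[1L], character(1)),
              origin_indices = r$origin_indices)
}

#' Acquisition metadata
#'
#' Frame interval and pixel size drive timestamps and scale bars; the
#' reference channel names the temporally stable structure (typically blood
#' vessels) used for scoring and alignment.
#'
#' @param frame_interval seconds per frame (> 0). Intravital two-photon
#'   acquisitions typically run at 2.5-15 frames per second; a value outside
#'   `[1/15, 1/2.5]` s triggers a warning, not an error.
#' @param pixel_size micrometres per pixel (> 0), or `NULL` if unknown
#'   (scale-bar overlays then refuse to run).
#' @param channel_names up to 3 channel labels.
#' @param reference_channel label of the scoring channel; must be one of
#'   `channel_names`.
#' @return an object of class `acquisition_meta`.
#' @export
acquisition_meta <- function(frame_interval, pixel_size = NULL,
                             channel_names = c("red", "green", "blue"),
                             reference_channel = channel_names[1L]) {
  if (!is.numeric(frame_interval) || length(frame_interval) != 1L ||
      !is.finite(frame_interval) || frame_interval <= 0)
    stop("frame_interval must be a single positive number of seconds")
  if (frame_interval < 1 / 15 || frame_interval > 1 / 2.5)
    warning(sprintf(
      "frame_interval %.4g s is outside the usual 2.5-15 fps range",
      frame_interval))
  if (!is.null(pixel_size)) {
    if (!is.numeric(pixel_size) || length(pixel_size) != 1L ||
        !is.finite(pixel_size) || pixel_size <= 0)
      stop("pixel_size must be a single positive number of micrometres")
  }
  if (length(channel_names) < 1L || length(channel_names) > 3L)
    stop("between 1 and 3 channel names are required")
  if (!reference_channel %in% channel_names)
    stop("reference_channel '", reference_channel,
         "' is not among channel_names")
  structure(list(frame_interval = frame_interval, pixel_size = pixel_size,
                 channel_names = as.character(channel_names),
                 reference_channel = reference_channel),
            class = "acquisition_meta")
}

#' Parse an acquisition metadata sidecar
#'
#' Reads a plain-text `key = value` file emulating a microscope TXT export.
#' Recognized keys: `frame_interval_s` (required), `pixel_size_um`,
#' `channels` (comma-separated), `reference_channel`. Unknown keys are
#' ignored with a warning.
#'
#' @param path path to the text file.
#' @return an [acquisition_meta()] object.
#' @export
parse_metadata <- function(path) {
  if (!file.exists(path)) stop("cannot read metadata file '", path, "'")
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    if (length(parts) < 2L) next
    key <- trimws(parts[1L])
    val <- trimws(paste(parts[-1L], collapse = "="))
    kv[[key]] <- val
  }
  known <- c("frame_interval_s", "pixel_size_um", "channels",
             "reference_channel")
  unknown <- setdiff(names(kv), known)
  if (length(unknown) > 0L)
    warning("ignoring unknown metadata key(s): ",
            paste(unknown, collapse = ", "))
  if (is.null(kv$frame_interval_s))
    stop("metadata file lacks required key 'frame_interval_s'")
  fi <- suppressWarnings(as.numeric(kv$frame_interval_s))
  if (is.na(fi)) stop("frame_interval_s is not numeric")
  if (fi <= 0) stop("frame_interval_s must be positive, got ", fi)
  ps <- NULL
  if (!is.null(kv$pixel_size_um)) {
    ps <- suppressWarnings(as.numeric(kv$pixel_size_um))
    if (is.na(ps)) stop("pixel_size_um is not numeric")
    if (ps <= 0) stop("pixel_size_um must be positive, got ", ps)
  }
  channels <- if (!is.null(kv$channels))
    trimws(strsplit(kv$channels, ",", fixed = TRUE)[[1L]])
  else c("red", "green", "blue")
  refch <- if (!is.null(kv$reference_channel)) kv$reference_channel
  else channels[1L]
  acquisition_meta(frame_interval = fi, pixel_size = ps,
                   channel_names = channels, reference_channel = refch)
}
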
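# 3x5 bitmap glyphs (rows top to bottom); rendering uses integer
# upscaling, so burn-in is deterministic across platforms
.glyphs <- list(
  "0" = c("111", "101", "101", "101", "111"),
  "1" = c("010", "110", "010", "010", "111"),
  "2" = c("111", "001", "111", "100", "111"),
  "3" = c("111", "001", "111", "001", "111"),
  "4" = c("101", "101", "111", "001", "001"),
  "5" = c("111", "100", "111", "001", "111"),
  "6" = c("111", "100", "111", "101", "111"),
  "7" = c("111", "001", "001", "010", "010"),
  "8" = c("111", "101", "111", "101", "111"),
  "9" = c("111", "101", "111", "001", "111"),
  ":" = c("000", "010", "000", "010", "000"),
  "." = c("000", "000", "000", "000", "010"),
  "u" = c("000", "101", "101", "101", "111"),
  "m" = c("000", "110", "111", "101", "101"),
  " " = c("000", "000", "000", "000", "000"))

# render a string into a binary matrix (1 = lit pixel)
render_text <- function(text, scale = 1L) {
  chars <- strsplit(text, "")[[1L]]
  cols <- lapply(chars, function(ch) {
    g <- .glyphs[[ch]]
    if (is.null(g)) g <- .glyphs[[" "]]
    m <- do.call(rbind, lapply(g, function(row)
      as.integer(strsplit(row, "")[[1L]])))
    cbind(m, 0L)  # 1px inter-glyph gap
  })
  m <- do.call(cbind, cols)
  if (scale > 1L)
    m <- m[rep(seq_len(nrow(m)), each = scale),
           rep(seq_len(ncol(m)), each = scale), drop = FALSE]
  m
}

# stamp a binary mask into every channel of one frame: black 1px outline,
# white glyph pixels
stamp_mask <- function(frames, t, mask, row0, col0) {
  d <- dim(frames)
  lit <- which(mask == 1L, arr.ind = TRUE)
  if (nrow(lit) == 0L) return(frames)
  rows <- row0 + lit[, 1L] - 1L
  cols <- col0 + lit[, 2L] - 1L
  ok <- rows >= 1L & rows <= d[1L] & cols >= 1L & cols <= d[2L]
  rows <- rows[ok]; cols <- cols[ok]
  for (ci in seq_len(d[3L])) {
    for (dr in -1:1) for (dc in -1:1) {
      rr <- rows + dr; cc <- cols + dc
      okk <- rr >= 1L & rr <= d[1L] & cc >= 1L & cc <= d[2L]
      frames[cbind(rr[okk], cc[okk], ci, t)] <- 0
    }
  }
  for (ci in seq_len(d[3L]))
    frames[cbind(rows, cols, ci, t)] <- 255
  frames
}

corner_origin <- function(position, H, W, mh, mw, margin = 2L) {
  switch(position,
         topleft = c(margin + 1L, margin + 1L),
         topright = c(margin + 1L, W - mw - margin + 1L),
         bottomleft = c(H - mh - margin + 1L, margin + 1L),
         bottomright = c(H - mh - margin + 1L, W - mw - margin + 1L),
         stop("unknown corner '", position, "'"))
}

#' Timestamp overlay specification
#'
#' @param position corner: `"topleft"`, `"topright"`, `"bottomleft"`,
#'   `"bottomright"`.
#' @param size glyph height in px (rounded to a multiple of 5; default 10).
#' @param apply `"burnin"` (pixels modified) or `"sidecar"` (annotation
#'   table only; pixels untouched).
#' @return an object of class `timestamp_spec`.
#' @export
timestamp_spec <- function(position = "topleft", size = 10L,
                           apply = c("burnin", "sidecar")) {
  apply <- match.arg(apply)
  structure(list(position = position, size = as.integer(size),
                 apply = apply, format = "MM:SS.mmm"),
            class = "timestamp_spec")
}

#' Format seconds as MM:SS.mmm
#' @param seconds non-negative time in seconds.
#' @return character timestamp, e.g. `"00:02.800"`.
#' @export
format_timestamp <- function(seconds) {
  mins <- floor(seconds / 60)
  secs <- seconds - 60 * mins
  # guard against 60.000 after rounding
  ms <- round(secs * 1000)
  mins <- mins + ms %/% 60000
  ms <- ms %% 60000
  sprintf("%02d:%02d.%03d", as.integer(mins), as.integer(ms %/% 1000),
          as.integer(ms %% 1000))
}

#' Burn removal-aware timestamps into a stack
#'
#' Each retained frame is annotated with its *original* acquisition time,
#' `origin_index * frame_interval` — so a frame that sat at position 6 of
#' the acquisition still reads `6 * interval` no matter how many earlier
#' frames were removed. A sidecar table is always produced; in burn-in
#' mode the time is additionally rendered into the pixels (white glyphs
#' with a black outline, built-in bitmap font).
#'
#' @param stack a `frame_stack`.
#' @param meta an [acquisition_meta()] with `frame_interval`.
#' @param spec a [timestamp_spec()].
#' @return list with `stack` (annotated or untouched `frame_stack`) and
#'   `sidecar` (data frame: `origin_index`, `position_index`, `time_s`,
#'   `label`).
#' @export
timestamp_overlay <- function(stack, meta, spec = timestamp_spec()) {
  stopifnot(inherits(stack, "frame_stack"),
            inherits(meta, "acquisition_meta"),
            inherits(spec, "timestamp_spec"))
  if (is.null(meta$frame_interval))
    stop("metadata lacks frame_interval; cannot timestamp")
  times <- stack$origin_indices * meta$frame_interval
  labels <- vapply(times, format_timestamp, character(1))
  sidecar <- data.frame(origin_index = stack$origin_indices,
                        position_index = seq_along(times) - 1L,
                        time_s = times, label = labels)
  if (spec$apply == "sidecar")
    return(list(stack = stack, sidecar = sidecar))
  d <- dim(stack$frames)
  scale <- max(1L, spec$size %/% 5L)
  frames <- stack$frames
  for (t in seq_len(d[4L])) {
    mask <- render_text(labels[t], scale)
    org <- corner_origin(spec$position, d[1L], d[2L], nrow(mask), ncol(mask))
    frames <- stamp_mask(frames, t, mask, org[1L], org[2L])
  }
  list(stack = frame_stack(frames, stack$channel_names,
                           stack$origin_indices),
       sidecar = sidecar)
}

#' Burn a physical scale bar into a stack
#'
#' Draws a horizontal bar of `round(length / pixel_size)` pixels with a
#' micrometre label in the chosen corner of every frame.
#'
#' @param stack a `frame_stack`.
#' @param meta an [acquisition_meta()] with `pixel_size` set.
#' @param length bar length in micrometres.
#' @param position corner (default `"bottomright"`).
#' @param apply `"burnin"` or `"sidecar"` (no pixel change; returns the
#'   computed bar geometry only).
#' @return list with `stack` and `bar` (list: `length_um`, `length_px`).
#' @export
scale_bar_overlay <- function(stack, meta, length, position = "bottomright",
                              apply = c("burnin", "sidecar")) {
  apply <- match.arg(apply)
  stopifnot(inherits(stack, "frame_stack"),
            inherits(meta, "acquisition_meta"))
  if (is.null(meta$pixel_size))
    stop("metadata lacks pixel_size; cannot draw a scale bar")
  d <- dim(stack$frames)
  bar_px <- round(length / meta$pixel_size)
  if (bar_px < 1L) stop("scale bar would be under one pixel")
  if (bar_px > d[2L] - 4L)
    stop("scale bar of ", bar_px, " px does not fit a ", d[2L],
         "-px-wide frame")
  bar <- list(length_um = length, length_px = as.integer(bar_px))
  if (apply == "sidecar") return(list(stack = stack, bar = bar))
  label_mask <- render_text(paste0(format(length), " um"))
  bar_mask <- matrix(1L, 3L, bar_px)
  mh <- nrow(bar_mask) + 1L + nrow(label_mask)
  mw <- max(ncol(bar_mask), ncol(label_mask))
  full <- matrix(0L, mh, mw)
  full[seq_len(nrow(bar_mask)), seq_len(ncol(bar_mask))] <- bar_mask
  full[nrow(bar_mask) + 1L + seq_len(nrow(label_mask)),
       seq_len(ncol(label_mask))] <- label_mask
  frames <- stack$frames
  for (t in seq_len(d[4L])) {
    org <- corner_origin(position, d[1L], d[2L], mh, mw)
    frames <- stamp_mask(frames, t, full, org[1L], org[2L])
  }
  list(stack = frame_stack(frames, stack$channel_names,
                           stack$origin_indices),
       bar = bar)
}
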
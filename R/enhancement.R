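#' Subtract scaled channel bleed-through
#'
#' Removes cross-contamination of dyes under simultaneous excitation (e.g.
#' CFP signal appearing in the YFP channel) by subtracting a scaled copy of
#' the contaminating channel, clipping at 0 and re-quantizing to 8 bits.
#'
#' @param target single-channel `frame_stack` to clean.
#' @param source single-channel `frame_stack` carrying the contaminating
#'   signal; same shape as `target`.
#' @param alpha non-negative spillover scale (default 1). The scale is
#'   user-set: estimating it requires single-dye control data.
#' @return a single-channel `frame_stack`.
#' @export
subtract_channel <- function(target, source, alpha = 1) {
  stopifnot(inherits(target, "frame_stack"), inherits(source, "frame_stack"))
  if (!identical(dim(target$frames), dim(source$frames)))
    stop("target and source stacks must share dimensions")
  if (dim(target$frames)[3L] != 1L)
    stop("subtract_channel expects single-channel stacks")
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0)
    stop("alpha must be a single non-negative number")
  frame_stack(clamp8(target$frames - alpha * source$frames),
              target$channel_names, target$origin_indices)
}

#' Projection configuration
#'
#' @param kind `"max"` or `"average"`.
#' @param window group size `w >= 2`; consecutive non-overlapping groups of
#'   `w` frames are collapsed into one output frame, trading frame rate for
#'   signal-to-noise (average) or extended field of view (max).
#' @return an object of class `projection_config`.
#' @export
projection_config <- function(kind = c("max", "average"), window = 2L) {
  kind <- match.arg(kind)
  window <- as.integer(window)
  if (is.na(window) || window < 2L) stop("projection window must be >= 2")
  structure(list(kind = kind, window = window), class = "projection_config")
}

#' Grouped intensity projection
#'
#' Collapses consecutive non-overlapping groups of `window` frames into one
#' frame per group by the per-pixel, per-channel maximum or (8-bit rounded)
#' average. A trailing partial group is projected as-is. The output frame
#' inherits the origin index of the first frame in its group.
#'
#' @param stack a `frame_stack`.
#' @param config a [projection_config()].
#' @return a `frame_stack` of `ceiling(T / window)` frames.
#' @export
project <- function(stack, config) {
  stopifnot(inherits(stack, "frame_stack"),
            inherits(config, "projection_config"))
  d <- dim(stack$frames)
  w <- config$window
  if (w > d[4L]) stop("projection window ", w, " exceeds stack length ", d[4L])
  n_out <- ceiling(d[4L] / w)
  out <- array(0, dim = c(d[1:3], n_out))
  origin <- integer(n_out)
  for (g in seq_len(n_out)) {
    idx <- ((g - 1L) * w + 1L):min(g * w, d[4L])
    blk <- matrix(stack$frames[, , , idx, drop = FALSE],
                  prod(d[1:3]), length(idx))
    out[, , , g] <- if (config$kind == "max")
      apply(blk, 1L, max) else clamp8(rowMeans(blk))
    origin[g] <- stack$origin_indices[idx[1L]]
  }
  frame_stack(out, stack$channel_names, origin)
}

#' Kalman filter parameters
#'
#' The causal per-pixel temporal smoother used to denoise a video without
#' reducing its frame count. In fixed-gain mode the estimate follows
#' `E_t = g * E_(t-1) + (1 - g) * obs_t` (exponential smoothing with
#' persistence `g`). In adaptive mode a scalar-state Kalman recursion
#' shrinks the gain over time from an initial variance equal to the
#' measurement noise `R = (rho * 255)^2`.
#'
#' @param gain persistence `g` in `[0, 1)`; `g = 0` is the identity
#'   filter. Default 0.8.
#' @param mode `"fixed"` or `"adaptive"`.
#' @param rho measurement-noise fraction of full scale in `(0, 1)`
#'   (adaptive mode, default 0.05).
#' @return an object of class `kalman_params`.
#' @export
kalman_params <- function(gain = 0.8, mode = c("fixed", "adaptive"),
                          rho = 0.05) {
  mode <- match.arg(mode)
  if (!is.numeric(gain) || length(gain) != 1L || gain < 0 || gain >= 1)
    stop("gain must lie in [0, 1)")
  if (!is.numeric(rho) || length(rho) != 1L || rho <= 0 || rho >= 1)
    stop("rho must lie in (0, 1)")
  structure(list(gain = gain, mode = mode, rho = rho),
            class = "kalman_params")
}

#' Kalman stack filter: causal temporal denoising
#'
#' Per pixel and channel, a causal recursion seeded with the first
#' observation smooths the intensity time course; the output keeps the
#' input's frame count (unlike projections, which trade frames for noise).
#' State is kept real-valued throughout and re-quantized to 8 bits only at
#' the end. Frame `t` of the output depends only on frames `<= t`.
#'
#' @param stack a `frame_stack`.
#' @param params a [kalman_params()].
#' @return a `frame_stack` with the same dimensions and origin indices.
#' @export
kalman_filter <- function(stack, params = kalman_params()) {
  stopifnot(inherits(stack, "frame_stack"),
            inherits(params, "kalman_params"))
  d <- dim(stack$frames)
  T <- d[4L]
  npx <- prod(d[1:3])
  obs <- matrix(stack$frames, npx, T)
  est <- matrix(0, npx, T)
  est[, 1L] <- obs[, 1L]
  if (params$mode == "fixed") {
    g <- params$gain
    if (T > 1L) for (t in 2:T)
      est[, t] <- g * est[, t - 1L] + (1 - g) * obs[, t]
  } else {
    R <- (params$rho * 255)^2
    V <- R
    if (T > 1L) for (t in 2:T) {
      K <- V / (V + R)
      est[, t] <- est[, t - 1L] + K * (obs[, t] - est[, t - 1L])
      V <- (1 - K) * V
    }
  }
  frame_stack(array(clamp8(est), dim = d), stack$channel_names,
              stack$origin_indices)
}
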
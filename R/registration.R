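#' Geometric transform models
#'
#' A `transform_model` maps coordinates of a moving frame onto its fixed
#' predecessor: `p_fixed = A %*% c(x, y, 1)` with `A` a 3 x 3 homogeneous
#' matrix and `(x, y)` 0-based (column, row) pixel coordinates. Four kinds
#' are supported, in increasing generality: `translation` (shift only),
#' `rigid` (shift + rotation), `scaled_rotation` (shift + rotation +
#' isotropic scale), `affine` (full 2 x 3 matrix: shift, rotation, shear,
#' skew, anisotropic scale). Translation is a special case of all of them,
#' and each kind is closed under composition.
#'
#' @param kind one of `"translation"`, `"rigid"`, `"scaled_rotation"`,
#'   `"affine"`.
#' @param dx,dy translation in pixels.
#' @param theta rotation in radians (rigid, scaled_rotation).
#' @param s isotropic scale (scaled_rotation).
#' @param matrix full 2 x 3 or 3 x 3 matrix (affine); overrides the other
#'   parameters.
#' @return an object of class `transform_model` with elements `kind`,
#'   `matrix` (3 x 3) and `params`.
#' @export
transform_model <- function(kind = c("translation", "rigid",
                                     "scaled_rotation", "affine"),
                            dx = 0, dy = 0, theta = 0, s = 1,
                            matrix = NULL) {
  kind <- match.arg(kind)
  if (kind == "affine" && !is.null(matrix)) {
    m <- rbind(matrix, c(0, 0, 1))[1:3, , drop = FALSE]
    if (!all(is.finite(m))) stop("affine matrix has non-finite entries")
    A <- m
    params <- list(dx = A[1L, 3L], dy = A[2L, 3L])
  } else {
    sc <- switch(kind, translation = 1, rigid = 1, scaled_rotation = s,
                 affine = s)
    R <- sc * rbind(c(cos(theta), -sin(theta)), c(sin(theta), cos(theta)))
    if (kind == "translation") R <- diag(2)
    A <- rbind(cbind(R, c(dx, dy)), c(0, 0, 1))
    params <- list(dx = dx, dy = dy, theta = theta, s = sc)
  }
  structure(list(kind = kind, matrix = A, params = params),
            class = "transform_model")
}

#' @export
print.transform_model <- function(x, ...) {
  p <- decompose_transform(x)
  cat(sprintf(
    "<transform_model:%s> dx=%.3f dy=%.3f theta=%.4f rad scale=%.4f\n",
    x$kind, p$dx, p$dy, p$theta, p$s))
  invisible(x)
}

# pull interpretable parameters out of the homogeneous matrix
decompose_transform <- function(model) {
  A <- model$matrix
  list(dx = A[1L, 3L], dy = A[2L, 3L],
       theta = atan2(A[2L, 1L], A[1L, 1L]),
       s = sqrt(abs(det(A[1:2, 1:2]))))
}

#' Compose two transform models
#'
#' `compose_transforms(outer, inner)` returns the model applying `inner`
#' first, then `outer` (matrix product `outer %*% inner`). The result's
#' kind is the more general of the two.
#'
#' @param outer,inner `transform_model`s.
#' @return a `transform_model`.
#' @export
compose_transforms <- function(outer, inner) {
  kinds <- c("translation", "rigid", "scaled_rotation", "affine")
  kind <- kinds[max(match(outer$kind, kinds), match(inner$kind, kinds))]
  A <- outer$matrix %*% inner$matrix
  out <- transform_model("affine", matrix = A)
  out$kind <- kind
  out
}

is_near_identity <- function(model, tol = 0.05) {
  max(abs(model$matrix - diag(3))) < tol
}

# sample img (matrix, rows = y + 1, cols = x + 1) at 0-based real-valued
# coordinates; bilinear interpolation, 0 outside the field
bilinear_sample <- function(img, xs, ys) {
  H <- nrow(img); W <- ncol(img)
  x0 <- floor(xs); y0 <- floor(ys)
  fx <- xs - x0; fy <- ys - y0
  val <- numeric(length(xs))
  px <- function(xi, yi) {
    inside <- xi >= 0 & xi <= W - 1 & yi >= 0 & yi <= H - 1
    v <- numeric(length(xi))
    v[inside] <- img[cbind(yi[inside] + 1L, xi[inside] + 1L)]
    v
  }
  val <- (1 - fx) * (1 - fy) * px(x0, y0) +
    fx * (1 - fy) * px(x0 + 1, y0) +
    (1 - fx) * fy * px(x0, y0 + 1) +
    fx * fy * px(x0 + 1, y0 + 1)
  val
}

# warp one channel under a transform model: out(q) = in(A^-1 q)
warp_affine <- function(img, A) {
  H <- nrow(img); W <- ncol(img)
  Ai <- solve(A)
  xo <- rep(0:(W - 1), each = H)
  yo <- rep(0:(H - 1), times = W)
  xs <- Ai[1L, 1L] * xo + Ai[1L, 2L] * yo + Ai[1L, 3L]
  ys <- Ai[2L, 1L] * xo + Ai[2L, 2L] * yo + Ai[2L, 3L]
  matrix(bilinear_sample(img, xs, ys), H, W)
}

# warp one channel under a dense displacement field: out(q) = in(q + d(q))
warp_field <- function(img, dx_field, dy_field) {
  H <- nrow(img); W <- ncol(img)
  xo <- rep(0:(W - 1), each = H)
  yo <- rep(0:(H - 1), times = W)
  xs <- xo + as.vector(dx_field)
  ys <- yo + as.vector(dy_field)
  matrix(bilinear_sample(img, xs, ys), H, W)
}

# FFT phase correlation: returns c(dx, dy) such that shifting `moving` by
# (dx, dy) best overlays it on `fixed`; parabolic sub-pixel refinement
phase_correlate <- function(moving, fixed) {
  # Hann window: suppresses wrap-around edges and the zero-filled borders
  # that frame removal / prior warping leave behind
  H <- nrow(moving); W <- ncol(moving)
  wy <- 0.5 - 0.5 * cos(2 * pi * (0:(H - 1)) / (H - 1))
  wx <- 0.5 - 0.5 * cos(2 * pi * (0:(W - 1)) / (W - 1))
  win <- outer(wy, wx)
  m <- (moving - mean(moving)) * win
  f <- (fixed - mean(fixed)) * win
  Fm <- stats::fft(m)
  Ff <- stats::fft(f)
  CP <- Ff * Conj(Fm)
  mag <- Mod(CP)
  CP <- CP / (mag + 1e-9 * max(mag))
  r <- Re(stats::fft(CP, inverse = TRUE))
  H <- nrow(r); W <- ncol(r)
  pk <- arrayInd(which.max(r), dim(r))
  py <- pk[1L]; px <- pk[2L]
  wrap <- function(i, n) ifelse(i - 1L > n / 2, i - 1L - n, i - 1L)
  dy <- wrap(py, H)
  dx <- wrap(px, W)
  # parabolic refinement through the peak (cyclic neighbours)
  sub <- function(vm, v0, vp) {
    den <- vm + vp - 2 * v0
    if (abs(den) < 1e-12) 0 else {
      d <- 0.5 * (vm - vp) / den
      max(-0.5, min(0.5, d))
    }
  }
  iy <- function(i) ((i - 1L) %% H) + 1L
  ix <- function(j) ((j - 1L) %% W) + 1L
  dy <- dy + sub(r[iy(py - 1L), px], r[py, px], r[iy(py + 1L), px])
  dx <- dx + sub(r[py, ix(px - 1L)], r[py, px], r[py, ix(px + 1L)])
  c(dx = dx, dy = dy)
}

# 2x2 block-mean downsample for the coarse-to-fine pyramid
downsample2 <- function(img) {
  H <- 2L * (nrow(img) %/% 2L); W <- 2L * (ncol(img) %/% 2L)
  img <- img[seq_len(H), seq_len(W), drop = FALSE]
  0.25 * (img[seq(1L, H, 2L), seq(1L, W, 2L)] +
            img[seq(2L, H, 2L), seq(1L, W, 2L)] +
            img[seq(1L, H, 2L), seq(2L, W, 2L)] +
            img[seq(2L, H, 2L), seq(2L, W, 2L)])
}

# Gauss-Newton (Lucas-Kanade style) refinement of the backward affine map
# B (fixed -> moving coordinates), minimizing the sum of squared intensity
# differences sum_q (moving(B q) - fixed(q))^2 over valid pixels.
# Returns the refined 3x3 matrix, or NULL when the normal equations are
# degenerate (featureless overlap).
lk_refine <- function(moving, fixed, B, iters = 50L, tol = 0.01) {
  H <- nrow(fixed); W <- ncol(fixed)
  gx <- (moving[, c(2:W, W)] - moving[, c(1L, 1:(W - 1L))]) / 2
  gy <- (moving[c(2:H, H), ] - moving[c(1L, 1:(H - 1L)), ]) / 2
  xo <- rep(0:(W - 1L), each = H)
  yo <- rep(0:(H - 1L), times = W)
  fv <- as.vector(fixed)
  for (it in seq_len(iters)) {
    xs <- B[1L, 1L] * xo + B[1L, 2L] * yo + B[1L, 3L]
    ys <- B[2L, 1L] * xo + B[2L, 2L] * yo + B[2L, 3L]
    ok <- xs >= 1 & xs <= W - 2 & ys >= 1 & ys <= H - 2
    if (sum(ok) < 64L) return(NULL)
    Iw <- bilinear_sample(moving, xs[ok], ys[ok])
    Gx <- bilinear_sample(gx, xs[ok], ys[ok])
    Gy <- bilinear_sample(gy, xs[ok], ys[ok])
    r <- fv[ok] - Iw
    J <- cbind(Gx * xo[ok], Gx * yo[ok], Gx, Gy * xo[ok], Gy * yo[ok], Gy)
    JtJ <- crossprod(J)
    delta <- tryCatch(solve(JtJ, crossprod(J, r)),
                      error = function(e) NULL)
    if (is.null(delta) || any(!is.finite(delta))) return(NULL)
    B[1L, ] <- B[1L, ] + delta[1:3]
    B[2L, ] <- B[2L, ] + delta[4:6]
    # displacement change at the far corner as the convergence measure
    step <- max(abs(delta[1L]) * W + abs(delta[2L]) * H + abs(delta[3L]),
                abs(delta[4L]) * W + abs(delta[5L]) * H + abs(delta[6L]))
    if (step < tol) break
  }
  B
}

# mean squared difference of moving warped under backward map B vs fixed
warp_cost <- function(moving, fixed, B) {
  H <- nrow(fixed); W <- ncol(fixed)
  xo <- rep(0:(W - 1L), each = H)
  yo <- rep(0:(H - 1L), times = W)
  xs <- B[1L, 1L] * xo + B[1L, 2L] * yo + B[1L, 3L]
  ys <- B[2L, 1L] * xo + B[2L, 2L] * yo + B[2L, 3L]
  ok <- xs >= 0 & xs <= W - 1 & ys >= 0 & ys <= H - 1
  if (sum(ok) < 16L) return(Inf)
  mean((bilinear_sample(moving, xs[ok], ys[ok]) - as.vector(fixed)[ok])^2)
}

# project the linear part of an affine map onto the rigid / scaled-rotation
# subgroup (polar decomposition), re-anchoring the translation so the image
# centre maps to the same point
project_to_subgroup <- function(A, kind, H, W) {
  A2 <- A[1:2, 1:2]
  sv <- svd(A2)
  R <- sv$u %*% t(sv$v)
  if (det(R) < 0) R <- sv$u %*% diag(c(1, -1)) %*% t(sv$v)
  A2p <- if (kind == "rigid") R else mean(sv$d) * R
  cen <- c((W - 1) / 2, (H - 1) / 2)
  tp <- A2 %*% cen + A[1:2, 3L] - A2p %*% cen
  rbind(cbind(A2p, tp), c(0, 0, 1))
}

#' Estimate the transform mapping a moving frame onto a fixed frame
#'
#' Translation is estimated by FFT phase correlation with parabolic
#' sub-pixel refinement. The richer kinds are estimated by coarse-to-fine
#' Gauss-Newton least squares on the affine warp parameters (the classic
#' pyramid approach of intensity-based stack registration), initialised at
#' the phase-correlation shift when that lowers the initial cost; rigid
#' and scaled-rotation results are obtained by polar projection of the
#' fitted linear part. When the least-squares system degenerates
#' (featureless overlap), estimation falls back to translation only with
#' a warning.
#'
#' @param moving,fixed single-channel numeric matrices of identical size.
#' @param kind transform family, see [transform_model()].
#' @param iters maximum Gauss-Newton iterations per pyramid level.
#' @param tol convergence tolerance: corner displacement change in px.
#' @return a `transform_model` mapping `moving` coordinates onto `fixed`.
#' @export
estimate_transform <- function(moving, fixed,
                               kind = c("translation", "rigid",
                                        "scaled_rotation", "affine"),
                               iters = 50L, tol = 0.01) {
  kind <- match.arg(kind)
  if (!identical(dim(moving), dim(fixed)))
    stop("moving and fixed frames must share dimensions")
  if (stats::var(as.vector(moving)) == 0 ||
      stats::var(as.vector(fixed)) == 0)
    stop("degenerate input: zero-variance frame")
  shift <- phase_correlate(moving, fixed)
  if (kind == "translation")
    return(transform_model("translation", dx = shift[1L], dy = shift[2L]))

  # image pyramid, coarsest first
  pyr <- list(list(m = moving, f = fixed))
  while (min(dim(pyr[[1L]]$m)) >= 64L && length(pyr) < 3L)
    pyr <- c(list(list(m = downsample2(pyr[[1L]]$m),
                       f = downsample2(pyr[[1L]]$f))), pyr)

  # initial backward map: identity vs the phase-correlation shift
  sc <- 2^(length(pyr) - 1L)
  B_id <- diag(3)
  B_pc <- diag(3); B_pc[1L, 3L] <- -shift[1L] / sc
  B_pc[2L, 3L] <- -shift[2L] / sc
  co <- pyr[[1L]]
  B <- if (warp_cost(co$m, co$f, B_pc) < warp_cost(co$m, co$f, B_id))
    B_pc else B_id
  for (lv in seq_along(pyr)) {
    if (lv > 1L) B[1:2, 3L] <- B[1:2, 3L] * 2
    refined <- lk_refine(pyr[[lv]]$m, pyr[[lv]]$f, B,
                         iters = iters, tol = tol)
    if (is.null(refined)) {
      warning("least-squares refinement degenerated; ",
              "falling back to translation-only")
      return(transform_model("translation", dx = shift[1L],
                             dy = shift[2L]))
    }
    B <- refined
  }
  A <- tryCatch(solve(B), error = function(e) NULL)
  if (is.null(A) || any(!is.finite(A))) {
    warning("estimated map not invertible; falling back to translation-only")
    return(transform_model("translation", dx = shift[1L], dy = shift[2L]))
  }
  if (kind %in% c("rigid", "scaled_rotation"))
    A <- project_to_subgroup(A, kind, nrow(fixed), ncol(fixed))
  out <- transform_model("affine", matrix = A)
  out$kind <- kind
  out
}

#' Resample one frame of a stack under a transform model
#'
#' All channels of frame `t` are inverse-warped with bilinear
#' interpolation; pixels mapped from outside the field are filled with 0
#' and the result is re-quantized to 8 bits (round half up).
#'
#' @param stack a `frame_stack`.
#' @param t 1-based positional frame index.
#' @param model a `transform_model` (must be invertible).
#' @return a new `frame_stack` with frame `t` replaced.
#' @export
apply_transform <- function(stack, t, model) {
  stopifnot(inherits(stack, "frame_stack"),
            inherits(model, "transform_model"))
  d <- dim(stack$frames)
  if (t < 1L || t > d[4L]) stop("frame index out of range")
  if (abs(det(model$matrix)) < 1e-12)
    stop("transform matrix is not invertible")
  frames <- stack$frames
  for (ci in seq_len(d[3L])) {
    img <- matrix(frames[, , ci, t], d[1L], d[2L])
    frames[, , ci, t] <- clamp8(warp_affine(img, model$matrix))
  }
  frame_stack(frames, stack$channel_names, stack$origin_indices)
}

#' Align a stack by propagation from the previous frame
#'
#' Frame 1 anchors the sequence. For every later frame, the transform of
#' the raw frame onto its already-aligned predecessor is estimated on the
#' reference channel; that estimate is therefore the cumulative model
#' mapping the raw frame into the anchor's coordinate system, and it is
#' applied to all channels. Because errors propagate through the chain,
#' gating artifact frames *before* alignment markedly improves the result.
#'
#' @param stack a `frame_stack` with `T >= 2`.
#' @param channel reference channel used for estimation.
#' @param kind transform family, see [transform_model()].
#' @param ... passed to [estimate_transform()].
#' @return list with `stack` (aligned `frame_stack`) and `models` (list of
#'   `T` cumulative `transform_model`s; the first is the identity).
#' @export
align_stack <- function(stack, channel = "red", kind = "translation", ...) {
  stopifnot(inherits(stack, "frame_stack"))
  d <- dim(stack$frames)
  if (d[4L] < 2L) stop("alignment needs at least 2 frames")
  ch <- get_channel(stack, channel)
  ci <- match(channel, stack$channel_names)
  frames <- stack$frames
  models <- vector("list", d[4L])
  models[[1L]] <- transform_model(kind)
  models[[1L]]$kind <- kind
  prev_aligned <- matrix(ch[, , 1L], d[1L], d[2L])
  for (t in 2:d[4L]) {
    raw <- matrix(ch[, , t], d[1L], d[2L])
    model <- tryCatch(
      estimate_transform(raw, prev_aligned, kind, ...),
      error = function(e) {
        warning("frame ", t, ": ", conditionMessage(e),
                "; propagating previous model")
        models[[t - 1L]]
      })
    models[[t]] <- model
    for (cc in seq_len(d[3L])) {
      img <- matrix(stack$frames[, , cc, t], d[1L], d[2L])
      frames[, , cc, t] <- clamp8(warp_affine(img, model$matrix))
    }
    prev_aligned <- matrix(frames[, , ci, t], d[1L], d[2L])
  }
  list(stack = frame_stack(frames, stack$channel_names,
                           stack$origin_indices),
       models = models)
}

#' Track a marker and measure its artifactual displacement
#'
#' Follows the local intensity patch around a marker from frame to frame
#' by SSD block matching within a search radius, and reports per-frame
#' displacement magnitudes and their sum — the total artifactual
#' displacement of the object. In a perfectly stable (or perfectly
#' aligned) video the sum is 0.
#'
#' @param stack a `frame_stack`.
#' @param marker numeric `c(x, y)` 0-based position in frame 1.
#' @param channel channel to track on.
#' @param patch odd patch edge in px (default 11).
#' @param search_radius search radius in px (default 15).
#' @param pixel_size µm per pixel, or `NULL` (µm column then omitted).
#' @return list with `track` data frame (`origin_index`, `x`, `y`,
#'   `displacement_px`, and `displacement_um` when `pixel_size` is given),
#'   `total_px` (and `total_um`), and `truncated` (TRUE if the patch left
#'   the field and the series was cut short).
#' @export
displacement_series <- function(stack, marker, channel = "green",
                                patch = 11L, search_radius = 15L,
                                pixel_size = NULL) {
  stopifnot(inherits(stack, "frame_stack"))
  ch <- get_channel(stack, channel)
  d <- dim(ch)
  hp <- patch %/% 2L
  x <- marker[1L]; y <- marker[2L]
  if (x < hp || x > d[2L] - 1L - hp || y < hp || y > d[1L] - 1L - hp)
    stop("marker patch does not fit inside the field")
  xs <- numeric(d[3L]); ys <- numeric(d[3L])
  xs[1L] <- x; ys[1L] <- y
  truncated <- FALSE
  used <- 1L
  P <- ch[(round(y) - hp):(round(y) + hp) + 1L,
          (round(x) - hp):(round(x) + hp) + 1L, 1L]
  for (t in 2:d[3L]) {
    img <- matrix(ch[, , t], d[1L], d[2L])
    cx <- round(xs[t - 1L]); cy <- round(ys[t - 1L])
    offs <- -search_radius:search_radius
    best <- Inf; bx <- NA_real_; by <- NA_real_
    ssd <- matrix(Inf, length(offs), length(offs))
    for (oy in seq_along(offs)) {
      yy <- cy + offs[oy]
      if (yy - hp < 0L || yy + hp > d[1L] - 1L) next
      for (ox in seq_along(offs)) {
        xx <- cx + offs[ox]
        if (xx - hp < 0L || xx + hp > d[2L] - 1L) next
        Q <- img[(yy - hp):(yy + hp) + 1L, (xx - hp):(xx + hp) + 1L]
        ssd[oy, ox] <- sum((P - Q)^2)
        if (ssd[oy, ox] < best) {
          best <- ssd[oy, ox]; bx <- xx; by <- yy; bo <- c(oy, ox)
        }
      }
    }
    if (!is.finite(best)) { truncated <- TRUE; break }
    sx <- 0; sy <- 0
    if (bo[2L] > 1L && bo[2L] < length(offs) &&
        all(is.finite(ssd[bo[1L], bo[2L] + c(-1L, 1L)]))) {
      den <- ssd[bo[1L], bo[2L] - 1L] + ssd[bo[1L], bo[2L] + 1L] -
        2 * ssd[bo[1L], bo[2L]]
      if (den > 1e-12)
        sx <- max(-0.5, min(0.5, 0.5 *
          (ssd[bo[1L], bo[2L] - 1L] - ssd[bo[1L], bo[2L] + 1L]) / den))
    }
    if (bo[1L] > 1L && bo[1L] < length(offs) &&
        all(is.finite(ssd[bo[1L] + c(-1L, 1L), bo[2L]]))) {
      den <- ssd[bo[1L] - 1L, bo[2L]] + ssd[bo[1L] + 1L, bo[2L]] -
        2 * ssd[bo[1L], bo[2L]]
      if (den > 1e-12)
        sy <- max(-0.5, min(0.5, 0.5 *
          (ssd[bo[1L] - 1L, bo[2L]] - ssd[bo[1L] + 1L, bo[2L]]) / den))
    }
    xs[t] <- bx + sx; ys[t] <- by + sy
    used <- t
  }
  xs <- xs[seq_len(used)]; ys <- ys[seq_len(used)]
  disp <- c(0, sqrt(diff(xs)^2 + diff(ys)^2))
  track <- data.frame(origin_index = stack$origin_indices[seq_len(used)],
                      x = xs, y = ys, displacement_px = disp)
  out <- list(track = track, total_px = sum(disp), truncated = truncated)
  if (!is.null(pixel_size)) {
    track$displacement_um <- disp * pixel_size
    out$track <- track
    out$total_um <- sum(disp) * pixel_size
  }
  out
}

#' Export per-frame transform models as a tidy table
#'
#' @param models list of `transform_model`s, as returned by
#'   [align_stack()].
#' @param origin_indices optional origin indices to attach.
#' @return data frame with kind, dx, dy, theta, s and the six affine
#'   entries per frame.
#' @export
transform_table <- function(models, origin_indices = NULL) {
  rows <- lapply(seq_along(models), function(i) {
    m <- models[[i]]
    p <- decompose_transform(m)
    A <- m$matrix
    data.frame(frame = i - 1L, kind = m$kind, dx = p$dx, dy = p$dy,
               theta = p$theta, s = p$s,
               a11 = A[1, 1], a12 = A[1, 2], a13 = A[1, 3],
               a21 = A[2, 1], a22 = A[2, 2], a23 = A[2, 3])
  })
  df <- do.call(rbind, rows)
  if (!is.null(origin_indices)) df$origin_index <- origin_indices
  df
}
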
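# seeded random 8-bit stack
random_stack <- function(T = 5L, H = 16L, W = 16L, C = 3L, seed = 1L) {
  set.seed(seed)
  frame_stack(array(sample(0:255, H * W * C * T, replace = TRUE),
                    dim = c(H, W, C, T)))
}

# a score_series with prescribed scores, bypassing image scoring, for
# exercising the gating filters in isolation
series_from_scores <- function(scores, origin_indices = seq_along(scores) - 1L) {
  structure(list(scores = as.numeric(scores),
                 origin_indices = as.integer(origin_indices),
                 policy = reference_policy("rfg", window = 3L),
                 channel = "red"),
            class = "score_series")
}

# clean static scene with known per-frame translations applied on top;
# returns the jittered stack plus the clean original and the shifts
jittered_scene <- function(T = 12L, H = 96L, W = 96L, max_shift = 5,
                           seed = 4L) {
  sc <- generate_scene(scene_config(T = T, H = H, W = W, rate_major = 0,
                                    rate_minor = 0, noise_sd = 2,
                                    cell_speed = 0, seed = seed))
  set.seed(seed + 1000L)
  jit <- cbind(runif(T, -max_shift, max_shift),
               runif(T, -max_shift, max_shift))
  jit[1L, ] <- 0
  frames <- sc$stack$frames
  for (t in seq_len(T)[-1L]) {
    A <- transform_model("translation", dx = jit[t, 1L],
                         dy = jit[t, 2L])$matrix
    for (ci in 1:3)
      frames[, , ci, t] <- ivmclean:::clamp8(
        ivmclean:::warp_affine(matrix(sc$stack$frames[, , ci, t], H, W), A))
  }
  list(stack = frame_stack(frames), clean = sc$stack, shifts = jit)
}

# brightest vessel pixel away from the border, as an (x, y) 0-based marker
vessel_marker <- function(stack, margin = 20L) {
  img <- get_channel(stack, "red")[, , 1L]
  H <- nrow(img); W <- ncol(img)
  sub <- img[(margin + 1L):(H - margin), (margin + 1L):(W - margin)]
  pk <- arrayInd(which.max(sub), dim(sub))
  c(x = pk[2L] + margin - 1L, y = pk[1L] + margin - 1L)
}
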
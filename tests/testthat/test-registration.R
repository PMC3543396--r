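vessel_image <- function(seed = 5L, H = 96L, W = 96L) {
  sc <- generate_scene(scene_config(T = 1L, H = H, W = W, rate_major = 0,
                                    rate_minor = 0, noise_sd = 0,
                                    seed = seed))
  get_channel(sc$stack, "red")[, , 1L]
}

test_that("a frame against itself estimates the identity for every kind", {
  img <- vessel_image()
  for (kind in c("translation", "rigid", "scaled_rotation", "affine")) {
    m <- estimate_transform(img, img, kind)
    expect_lt(max(abs(m$matrix - diag(3))), 0.05)
    expect_equal(m$kind, kind)
  }
  expect_error(estimate_transform(matrix(0, 96, 96), img, "translation"),
               "zero-variance")
})

test_that("planted translations are recovered within half a pixel", {
  img <- vessel_image()
  shifts <- rbind(c(3, -2), c(-4.4, 1.3), c(5, 5), c(0.6, -4.8))
  for (i in seq_len(nrow(shifts))) {
    A <- transform_model("translation", dx = shifts[i, 1L],
                         dy = shifts[i, 2L])$matrix
    moved <- ivmclean:::warp_affine(img, A)
    est <- estimate_transform(img, moved, "translation")
    expect_lt(abs(est$params$dx - shifts[i, 1L]), 0.5)
    expect_lt(abs(est$params$dy - shifts[i, 2L]), 0.5)
  }
  # graceful degradation under heavy noise (sigma = 10 intensity levels)
  set.seed(2)
  A <- transform_model("translation", dx = 3, dy = -2)$matrix
  noisy <- ivmclean:::clamp8(ivmclean:::warp_affine(img, A) +
                               matrix(rnorm(96 * 96, 0, 10), 96, 96))
  est <- estimate_transform(img, noisy, "translation")
  expect_lt(abs(est$params$dx - 3), 1)
  expect_lt(abs(est$params$dy + 2), 1)
})

test_that("planted affine, rigid and scaled-rotation maps are recovered", {
  Ash <- rbind(c(1, 0.1, 2), c(0.05, 1, -1), c(0, 0, 1))
  for (seed in c(1L, 3L, 5L)) {
    img <- vessel_image(seed)
    est <- estimate_transform(img, ivmclean:::warp_affine(img, Ash),
                              "affine")
    expect_lt(norm(est$matrix - Ash, "F") / norm(Ash, "F"), 0.02)
  }
  img <- vessel_image()
  Ar <- transform_model("rigid", dx = 1.5, dy = -1, theta = 0.05)$matrix
  estr <- estimate_transform(img, ivmclean:::warp_affine(img, Ar), "rigid")
  expect_lt(norm(estr$matrix - Ar, "F") / norm(Ar, "F"), 0.02)
  expect_equal(ivmclean:::decompose_transform(estr)$s, 1)
  As <- transform_model("scaled_rotation", dx = 1, dy = 2, theta = 0.03,
                        s = 1.05)$matrix
  ests <- estimate_transform(img, ivmclean:::warp_affine(img, As),
                             "scaled_rotation")
  expect_lt(norm(ests$matrix - As, "F") / norm(As, "F"), 0.02)
})

test_that("apply_transform moves deltas exactly and round-trips interiors", {
  st <- random_stack(T = 2L, H = 32L, W = 32L, C = 1L, seed = 131L)
  ident <- transform_model("translation")
  expect_identical(apply_transform(st, 1L, ident)$frames, st$frames)
  # integer translation of a delta image: moved exactly, no blur
  frames <- array(0, c(32, 32, 1, 1))
  frames[16, 16, 1, 1] <- 200
  delta <- frame_stack(frames)
  moved <- apply_transform(delta, 1L,
                           transform_model("translation", dx = 4, dy = -3))
  expect_equal(moved$frames[13, 20, 1, 1], 200)  # y 15->12, x 15->19 (0-based)
  expect_equal(sum(moved$frames), 200)
  # integer forward-then-inverse translation recovers the interior within
  # one intensity level (bilinear weights collapse to exact sampling)
  fw <- apply_transform(st, 1L, transform_model("translation",
                                                dx = 3, dy = -2))
  bk <- apply_transform(fw, 1L, transform_model("translation",
                                                dx = -3, dy = 2))
  interior <- bk$frames[6:27, 6:27, 1L, 1L] - st$frames[6:27, 6:27, 1L, 1L]
  expect_lte(max(abs(interior)), 1)
  # fractional round trip on a smooth image stays close after two
  # interpolations
  vs <- generate_scene(scene_config(T = 1L, H = 64L, W = 64L,
                                    rate_major = 0, rate_minor = 0,
                                    noise_sd = 0, seed = 6L))$stack
  fw2 <- apply_transform(vs, 1L, transform_model("translation",
                                                 dx = 2.3, dy = -1.7))
  bk2 <- apply_transform(fw2, 1L, transform_model("translation",
                                                  dx = -2.3, dy = 1.7))
  int2 <- bk2$frames[10:55, 10:55, 1L, 1L] - vs$frames[10:55, 10:55, 1L, 1L]
  expect_lt(mean(abs(int2)), 3)
  expect_error(apply_transform(st, 1L,
                               transform_model("affine",
                                               matrix = matrix(0, 2, 3))),
               "invertible")
})

test_that("transform composition stays in-kind and matches matrices", {
  a <- transform_model("translation", dx = 2, dy = 3)
  b <- transform_model("translation", dx = -1, dy = 1)
  ab <- compose_transforms(a, b)
  expect_equal(ab$kind, "translation")
  expect_equal(ab$matrix, a$matrix %*% b$matrix)
  r <- transform_model("rigid", dx = 1, dy = 0, theta = 0.1)
  ar <- compose_transforms(a, r)
  expect_equal(ar$kind, "rigid")
})

test_that("alignment removes planted jitter and is idempotent", {
  js <- jittered_scene(T = 12L, seed = 4L)
  al <- align_stack(js$stack, "red", "translation")
  est <- t(vapply(al$models, function(m) c(m$matrix[1L, 3L], m$matrix[2L, 3L]),
                  numeric(2)))
  expect_lt(max(abs(est - (-js$shifts))), 0.5)
  marker <- vessel_marker(js$clean)
  before <- displacement_series(js$stack, marker, channel = "red")
  after <- displacement_series(al$stack, marker, channel = "red")
  expect_lt(max(after$track$displacement_px), 0.5)
  expect_lt(after$total_px, 0.1 * before$total_px)
  # aligning an aligned stack is a near-no-op
  al2 <- align_stack(al$stack, "red", "translation")
  devs <- vapply(al2$models, function(m) max(abs(m$matrix - diag(3))),
                 numeric(1))
  expect_lt(max(devs), 0.5)
  # pure translation barely changes interior intensity statistics
  mid <- function(s) mean(s$frames[20:77, 20:77, 1L, 2L])
  expect_lt(abs(mid(al$stack) - mid(js$clean)) / mid(js$clean), 0.05)
})

test_that("displacement tracking follows planted sinusoidal drift", {
  sc <- generate_scene(scene_config(T = 20L, H = 96L, W = 96L,
                                    rate_major = 0, rate_minor = 0,
                                    noise_sd = 0, cell_speed = 0, seed = 8L))
  # static scene: zero displacement everywhere
  marker <- vessel_marker(sc$stack)
  ds0 <- displacement_series(sc$stack, marker, channel = "red")
  expect_lt(ds0$total_px, 0.5)
  # planted sinusoid: amplitude 4 px, period 10 frames, x only
  amp <- 4; per <- 10
  frames <- sc$stack$frames
  xpos <- amp * sin(2 * pi * (0:19) / per)
  for (t in 2:20) {
    A <- transform_model("translation", dx = xpos[t], dy = 0)$matrix
    for (ci in 1:3)
      frames[, , ci, t] <- ivmclean:::clamp8(
        ivmclean:::warp_affine(matrix(sc$stack$frames[, , ci, t], 96, 96), A))
  }
  drifted <- frame_stack(frames)
  ds <- displacement_series(drifted, marker, channel = "red")
  analytic <- sum(abs(diff(xpos)))
  expect_lt(abs(ds$total_px - analytic) / analytic, 0.1)
  expect_false(ds$truncated)
})
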
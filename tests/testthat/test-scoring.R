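test_that("ssd_score matches forced arithmetic and the per-pixel loop", {
  expect_equal(ssd_score(matrix(7, 4, 4), matrix(7, 4, 4)), 0)
  expect_equal(ssd_score(matrix(0, 2, 2), matrix(1:4, 2, 2, byrow = TRUE)),
               (1 + 4 + 9 + 16) / 4)
  set.seed(31)
  a <- matrix(sample(0:255, 64 * 64, TRUE), 64, 64)
  b <- matrix(sample(0:255, 64 * 64, TRUE), 64, 64)
  acc <- 0
  for (i in 1:64) for (j in 1:64) acc <- acc + (a[i, j] - b[i, j])^2
  expect_equal(ssd_score(a, b), acc / (64 * 64))
  expect_error(ssd_score(a, matrix(0, 3, 3)), "dimensions")
})

test_that("build_reference truncates windows at the boundaries", {
  st <- random_stack(T = 5L, H = 6L, W = 6L, C = 1L, seed = 41L)
  pol <- reference_policy("rfg", window = 3L)
  # t = 1: window would reach frame 0; truncates to frames {1, 2}
  expect_equal(build_reference(st, pol, 1L),
               (st$frames[, , 1L, 1L] + st$frames[, , 1L, 2L]) / 2)
  # interior: full 3-frame mean
  expect_equal(build_reference(st, pol, 3L),
               (st$frames[, , 1L, 2L] + st$frames[, , 1L, 3L] +
                  st$frames[, , 1L, 4L]) / 3)
  # n = 5 windowed mean vs explicit loop at every position
  pol5 <- reference_policy("rfg", window = 5L)
  for (t in 1:5) {
    lo <- max(1L, t - 2L); hi <- min(5L, t + 2L)
    ref <- matrix(0, 6, 6)
    for (k in lo:hi) ref <- ref + st$frames[, , 1L, k]
    expect_equal(build_reference(st, pol5, t), ref / (hi - lo + 1L))
  }
  # single mode returns the designated frame
  expect_equal(build_reference(st, reference_policy("single",
                                                    single_index = 2L), 5L),
               st$frames[, , 1L, 3L])
  # constant stack: any policy returns the constant grid
  cstack <- frame_stack(array(37, c(4, 4, 1, 6)))
  expect_equal(build_reference(cstack, pol5, 2L), matrix(37, 4, 4))
})

test_that("score_stack equals the brute-force per-frame loop (both modes)", {
  st <- random_stack(T = 20L, H = 64L, W = 64L, C = 3L, seed = 51L)
  for (pol in list(reference_policy("rfg", window = 5L),
                   reference_policy("rfg", window = 15L),
                   reference_policy("single", single_index = 7L))) {
    ser <- score_stack(st, "green", pol)
    chs <- split_channels(st)
    brute <- vapply(1:20, function(t)
      ssd_score(matrix(chs$green$frames[, , 1L, t], 64, 64),
                build_reference(chs$green, pol, t)), numeric(1))
    expect_equal(ser$scores, brute, tolerance = 1e-12)
  }
})

test_that("impulse frame in a constant stack scores by the closed form", {
  # constant stack with one frame deviating uniformly by v: under an
  # interior rfg window of n, the impulse scores (v (n-1)/n)^2 and each
  # window neighbour scores (v/n)^2
  v <- 60; n <- 5L; T <- 15L
  frames <- array(100, c(8, 8, 1, T))
  frames[, , 1L, 8L] <- 100 + v
  st <- frame_stack(frames)
  ser <- score_stack(st, "gray", reference_policy("rfg", window = n))
  expect_equal(ser$scores[8L], (v * (n - 1) / n)^2)
  expect_equal(ser$scores[7L], (v / n)^2)
  expect_equal(ser$scores[10L], (v / n)^2)
  expect_equal(ser$scores[3L], 0)
  # the impulse scores strictly above every other frame
  expect_true(all(ser$scores[8L] > ser$scores[-8L]))
  # single-reference mode scores 0 at its own reference frame
  ser1 <- score_stack(st, "gray", reference_policy("single",
                                                   single_index = 2L))
  expect_equal(ser1$scores[3L], 0)
})

test_that("scores are invariant to adding a constant image to all frames", {
  set.seed(61)
  st <- frame_stack(array(sample(0:200, 12 * 12 * 10, TRUE),
                          c(12, 12, 1, 10)))
  set.seed(62)
  offset <- array(sample(0:40, 144, TRUE), c(12, 12, 1, 10))  # recycled:
  # the same 12 x 12 offset image is added to every frame
  shifted <- frame_stack(st$frames + offset)
  pol <- reference_policy("rfg", window = 5L)
  expect_equal(score_stack(st, "gray", pol)$scores,
               score_stack(shifted, "gray", pol)$scores, tolerance = 1e-12)
})

test_that("score_report bins sum to one and match brute-force binning", {
  expect_equal(score_report(series_from_scores(c(0, 4)), bins = 50L)$histogram |>
                 (\(h) c(sum(h$relative_frequency > 0),
                         sum(h$relative_frequency)))(),
               c(2, 1))
  set.seed(71)
  s <- runif(200, 0, 100)
  rep50 <- score_report(series_from_scores(s), bins = 50L)
  expect_equal(sum(rep50$histogram$relative_frequency), 1)
  breaks <- seq(min(s), max(s), length.out = 51L)
  brute <- hist(s, breaks = breaks, plot = FALSE)$counts / length(s)
  expect_equal(rep50$histogram$relative_frequency, brute)
  expect_equal(rep50$trace$score, s)
})

test_that("rfg traces are flatter than single-reference under drift", {
  sc <- generate_scene(scene_config(T = 120L, H = 48L, W = 48L,
                                    rate_major = 0, rate_minor = 0,
                                    noise_sd = 2, drift_amplitude = 3,
                                    drift_period = 40L, seed = 81L))
  rfg <- score_stack(sc$stack, "red", reference_policy("rfg", window = 15L))
  sng <- score_stack(sc$stack, "red",
                     reference_policy("single", single_index = 0L))
  detrended_var <- function(s) stats::var(s$scores - stats::runmed(s$scores, 31L))
  expect_lt(detrended_var(rfg), detrended_var(sng))
})

test_that("policy invariants are enforced", {
  expect_error(reference_policy("rfg", window = 4L), "odd")
  expect_error(reference_policy("rfg", window = 1L), ">= 3")
  st <- random_stack(T = 5L, C = 1L)
  expect_error(score_stack(st, "gray", reference_policy("rfg", window = 7L)),
               "exceeds")
  expect_error(score_stack(st, "gray",
                           reference_policy("single", single_index = 9L)),
               "out of range")
  expect_error(score_stack(st, "magenta"), "unknown channel")
})
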
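test_that("percentile gate follows the nearest-rank convention", {
  ser <- series_from_scores(1:10)
  sel <- percentile_gate(ser, 60)
  expect_equal(sel$kept, 0:5)     # frames scoring 1..6
  expect_equal(sel$removed, 6:9)  # frames scoring 7..10
  expect_equal(percentile_gate(series_from_scores(rep(3, 7)), 40)$removed,
               integer(0))
  expect_equal(percentile_gate(ser, 100)$removed, integer(0))
  expect_error(percentile_gate(ser, 0), "\\(0, 100\\]")
})

test_that("percentile gate agrees with brute-force sort-and-threshold", {
  set.seed(91)
  for (rep in 1:50) {
    T <- sample(5:60, 1)
    s <- runif(T, 0, 1000)
    P <- sample(c(10, 25, 50, 60, 75, 90, 100), 1)
    sel <- percentile_gate(series_from_scores(s), P)
    thr <- sort(s)[ceiling(P / 100 * T)]
    expect_equal(sel$kept, which(s <= thr) - 1L)
    # distinct scores: exactly ceiling(P/100 * T) frames kept
    expect_equal(length(sel$kept), ceiling(P / 100 * T))
  }
})

test_that("neighbor filter removes the group maximum, earliest on ties", {
  sel <- neighbor_max_filter(series_from_scores(c(1, 9, 2, 3, 8, 4)), 3L)
  expect_equal(sel$removed, c(1L, 4L))
  # tie rule: earliest of the equal maxima goes
  expect_equal(neighbor_max_filter(series_from_scores(c(5, 5, 5)), 3L)$removed,
               0L)
  # trailing singleton is never removed
  sel7 <- neighbor_max_filter(series_from_scores(c(1, 2, 3, 4, 5, 6, 100)), 3L)
  expect_false(6L %in% sel7$removed)
  expect_equal(sel7$removed, c(2L, 5L))
  expect_error(neighbor_max_filter(series_from_scores(1:10), 4L), "odd")
})

test_that("neighbor filter removal count matches the partition formula", {
  set.seed(101)
  for (rep in 1:40) {
    T <- sample(6:80, 1)
    n <- sample(c(3L, 5L, 7L), 1)
    if (n > T) next
    sel <- neighbor_max_filter(series_from_scores(runif(T)), n)
    expected <- T %/% n + as.integer(T %% n >= 2L)
    expect_equal(length(sel$removed), expected)
    # gating never reorders: kept indices strictly increasing
    expect_true(all(diff(sel$kept) > 0))
  }
})

test_that("double filtering catches consecutive artifacts single passes miss", {
  # forced example: two adjacent high scores at positions 1 and 2
  ser <- series_from_scores(c(1, 9, 8, 1, 2, 1))
  single <- gate_series(ser, gate_config(percentile_cutoff = NULL,
                                         neighbor_group = 3L, passes = 1L))
  expect_equal(single$removed, c(1L, 4L))     # 8 at position 2 survives
  dbl <- gate_series(ser, gate_config(percentile_cutoff = NULL,
                                      neighbor_group = 3L, passes = 2L))
  expect_true(all(c(1L, 2L) %in% dbl$removed))
  expect_equal(dbl$removed, c(1L, 2L, 4L))
  expect_equal(sort(c(dbl$kept, dbl$removed)), 0:5)
  # pass provenance is recorded
  expect_equal(dbl$reason$pass[dbl$reason$origin_index == 2L], 2L)
  # a clean constant series still loses the tie-rule minimum per group in
  # pass 2 (documented over-removal)
  clean <- gate_series(series_from_scores(rep(1, 6)),
                       gate_config(percentile_cutoff = NULL,
                                   neighbor_group = 3L, passes = 2L))
  expect_equal(clean$removed, c(0L, 1L, 3L))
})

test_that("double filtering with rescoring cleans adjacent planted artifacts", {
  sc <- generate_scene(scene_config(
    T = 60L, H = 48L, W = 48L, rate_minor = 0, noise_sd = 2,
    major_types = "shift", major_shift = c(8, 16),
    major_indices = c(21L, 22L, 40L), seed = 7L))  # 21 and 22 share a group of 3
  pol <- reference_policy("rfg", window = 5L)
  single <- gate_stack(sc$stack, "red", pol,
                       gate_config(percentile_cutoff = NULL,
                                   neighbor_group = 3L, passes = 1L))
  m1 <- evaluate_gating(single$selection, sc$truth)
  # one relative-maximum pass cannot remove two artifacts out of one group
  expect_lt(m1$recall, 1)
  dbl <- double_filter(sc$stack, "red", pol,
                       gate_config(percentile_cutoff = NULL,
                                   neighbor_group = 3L, passes = 2L))
  m2 <- evaluate_gating(dbl$selection, sc$truth)
  expect_equal(m2$recall, 1)
  expect_equal(m2$residual_artifact_rate, 0)
})

test_that("apply_selection keeps origin indices and is idempotent", {
  st <- random_stack(T = 10L, H = 8L, W = 8L, C = 1L, seed = 111L)
  ser <- series_from_scores(rep(1, 10))
  all_sel <- percentile_gate(ser, 100)
  expect_identical(apply_selection(st, all_sel)$frames, st$frames)
  one <- ivmclean:::new_selection(7L, setdiff(0:9, 7L),
                                  ivmclean:::empty_reason())
  kept <- apply_selection(st, one)
  expect_equal(n_frames(kept), 1L)
  expect_equal(kept$origin_indices, 7L)
  expect_identical(apply_selection(kept, one)$frames, kept$frames)
  bad <- ivmclean:::new_selection(42L, 0:9, ivmclean:::empty_reason())
  expect_error(apply_selection(st, bad), "unknown origin")
})

test_that("evaluate_gating computes the published-style rates", {
  truth <- list(frames = data.frame(
    origin_index = 0:999,
    label = c(rep("major", 398), rep("good", 602))))
  # all artifacts removed plus 2 good frames
  sel <- ivmclean:::new_selection(kept = 400:999,
                                  removed = 0:399,
                                  ivmclean:::empty_reason())
  m <- evaluate_gating(sel, truth)
  expect_equal(m$artifact_rate_before, 0.398)
  expect_equal(m$residual_artifact_rate, 0)
  expect_equal(m$recall, 1)
  expect_equal(m$false_positive_rate, 2 / 602)
  # keep everything: residual rate equals the artifact rate
  keep_all <- ivmclean:::new_selection(0:999, integer(0),
                                       ivmclean:::empty_reason())
  expect_equal(evaluate_gating(keep_all, truth)$residual_artifact_rate, 0.398)
  # 600 kept containing 2 artifacts
  sel2 <- ivmclean:::new_selection(kept = c(0:1, 402:999),
                                   removed = c(2:401),
                                   ivmclean:::empty_reason())
  expect_equal(evaluate_gating(sel2, truth)$residual_artifact_rate, 2 / 600)
})

test_that("gate_config validates its invariants", {
  expect_error(gate_config(percentile_cutoff = NULL, neighbor_group = NULL),
               "at least one")
  expect_error(gate_config(percentile_cutoff = 120), "\\(0, 100\\]")
  expect_error(gate_config(neighbor_group = 4L), "odd")
  expect_error(gate_config(passes = 3L), "1 or 2")
  expect_error(double_filter(random_stack(), config = gate_config(passes = 1L)),
               "passes = 2")
})
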
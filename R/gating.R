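#' Gate configuration
#'
#' Which artifact filters to apply and how. The percentile filter keeps the
#' lowest-scoring `P`% of frames; the n-neighbor relative-maximum filter
#' removes, within each consecutive non-overlapping group of `n` frames, the
#' single highest-scoring frame. A single neighbor pass cannot eliminate two
#' consecutive distorted frames, which is what `passes = 2` (double
#' filtering) is for.
#'
#' @param percentile_cutoff keep percentile `P` in `(0, 100]`, or `NULL` to
#'   skip the percentile filter. The demonstrated headline setting is 60.
#' @param neighbor_group odd group size `n` (3, 5, 7, ...), or `NULL` to
#'   skip the neighbor filter.
#' @param passes 1 or 2; 2 re-applies the same filter(s) to the retained
#'   sequence.
#' @param rescore_between_passes if `TRUE`, scores (and rolling references)
#'   are recomputed on the retained stack before pass 2; if `NULL`
#'   (default), resolved to `TRUE` for rfg scoring and `FALSE` for
#'   single-reference scoring, since only rolling references change when
#'   frames are removed.
#' @return an object of class `gate_config`.
#' @export
gate_config <- function(percentile_cutoff = 60, neighbor_group = NULL,
                        passes = 1L, rescore_between_passes = NULL) {
  if (is.null(percentile_cutoff) && is.null(neighbor_group))
    stop("at least one of percentile_cutoff / neighbor_group is required")
  if (!is.null(percentile_cutoff)) {
    if (!is.numeric(percentile_cutoff) || length(percentile_cutoff) != 1L ||
        is.na(percentile_cutoff) ||
        percentile_cutoff <= 0 || percentile_cutoff > 100)
      stop("percentile_cutoff must lie in (0, 100]")
  }
  if (!is.null(neighbor_group)) {
    neighbor_group <- as.integer(neighbor_group)
    if (length(neighbor_group) != 1L || is.na(neighbor_group) ||
        neighbor_group < 3L || neighbor_group %% 2L == 0L)
      stop("neighbor_group must be an odd integer >= 3")
  }
  passes <- as.integer(passes)
  if (!passes %in% c(1L, 2L)) stop("passes must be 1 or 2")
  if (passes == 2L && is.null(neighbor_group) && is.null(percentile_cutoff))
    stop("passes = 2 requires a configured filter")
  structure(list(percentile_cutoff = percentile_cutoff,
                 neighbor_group = neighbor_group, passes = passes,
                 rescore_between_passes = rescore_between_passes),
            class = "gate_config")
}

new_selection <- function(kept, removed, reason) {
  kept <- sort(as.integer(kept))
  removed <- sort(as.integer(removed))
  if (length(intersect(kept, removed)) > 0L)
    stop("kept and removed frame sets overlap")
  structure(list(kept = kept, removed = removed, reason = reason),
            class = "frame_selection")
}

#' @export
print.frame_selection <- function(x, ...) {
  cat(sprintf("<frame_selection> %d kept / %d removed of %d frames\n",
              length(x$kept), length(x$removed),
              length(x$kept) + length(x$removed)))
  if (nrow(x$reason) > 0L)
    print(utils::head(x$reason, 10L))
  invisible(x)
}

empty_reason <- function() {
  data.frame(origin_index = integer(0), filter = character(0),
             pass = integer(0))
}

#' Percentile gate: reject the highest dissimilarity scores
#'
#' The threshold is the nearest-rank P-th percentile of the scores: the
#' value at rank `ceiling(P/100 * T)` of the ascending sort. Frames scoring
#' at most the threshold are kept; with all-distinct scores exactly
#' `ceiling(P/100 * T)` frames survive.
#'
#' @param series a `score_series`.
#' @param P keep percentile in `(0, 100]`.
#' @param pass pass number recorded in the removal provenance.
#' @return a `frame_selection` over the series' origin indices.
#' @export
percentile_gate <- function(series, P, pass = 1L) {
  stopifnot(inherits(series, "score_series"))
  T <- length(series$scores)
  if (T == 0L) stop("empty score series")
  if (!is.numeric(P) || P <= 0 || P > 100) stop("P must lie in (0, 100]")
  thr <- sort(series$scores)[ceiling(P / 100 * T)]
  keep <- series$scores <= thr
  removed <- series$origin_indices[!keep]
  new_selection(series$origin_indices[keep], removed,
                if (length(removed) == 0L) empty_reason() else
                  data.frame(origin_index = removed, filter = "percentile",
                             pass = as.integer(pass)))
}

#' n-neighbor relative-maximum filter
#'
#' Frames are partitioned in temporal order into consecutive
#' non-overlapping groups of `n`; within each group the single frame with
#' the highest score is removed (ties remove the earliest). A trailing
#' partial group of size >= 2 is still filtered; a trailing singleton is
#' kept.
#'
#' @param series a `score_series`.
#' @param n odd group size, `3 <= n <= T`.
#' @param pass pass number recorded in the removal provenance.
#' @return a `frame_selection`.
#' @export
neighbor_max_filter <- function(series, n, pass = 1L) {
  stopifnot(inherits(series, "score_series"))
  T <- length(series$scores)
  n <- as.integer(n)
  if (is.na(n) || n < 3L || n %% 2L == 0L || n > T)
    stop("group size must be an odd integer with 3 <= n <= T")
  groups <- split(seq_len(T), ceiling(seq_len(T) / n))
  removed_pos <- integer(0)
  for (g in groups) {
    if (length(g) < 2L) next
    removed_pos <- c(removed_pos, g[which.max(series$scores[g])])
  }
  removed <- series$origin_indices[removed_pos]
  new_selection(series$origin_indices[-removed_pos], removed,
                if (length(removed) == 0L) empty_reason() else
                  data.frame(origin_index = removed, filter = "neighbor",
                             pass = as.integer(pass)))
}

# one filtering pass over a score series: percentile first, then the
# neighbor filter on the survivors (the two are complementary: a low
# percentile alone would discard too many good frames)
gate_pass <- function(series, config, pass = 1L) {
  reason <- empty_reason()
  cur <- series
  if (!is.null(config$percentile_cutoff)) {
    sel <- percentile_gate(cur, config$percentile_cutoff, pass = pass)
    reason <- rbind(reason, sel$reason)
    keep <- cur$origin_indices %in% sel$kept
    cur <- restrict_series(cur, keep)
  }
  if (!is.null(config$neighbor_group) &&
      length(cur$scores) >= config$neighbor_group) {
    sel <- neighbor_max_filter(cur, config$neighbor_group, pass = pass)
    reason <- rbind(reason, sel$reason)
    keep <- cur$origin_indices %in% sel$kept
    cur <- restrict_series(cur, keep)
  }
  new_selection(cur$origin_indices,
                setdiff(series$origin_indices, cur$origin_indices), reason)
}

restrict_series <- function(series, keep) {
  structure(list(scores = series$scores[keep],
                 origin_indices = series$origin_indices[keep],
                 policy = series$policy, channel = series$channel),
            class = "score_series")
}

#' Gate a score series, optionally twice, without rescoring
#'
#' Applies the configured filter(s) to the series; with `passes = 2` the
#' same filter(s) run again on the retained subsequence using the pass-1
#' scores. Use [gate_stack()] when pass 2 should rebuild rolling references
#' on the retained frames.
#'
#' @param series a `score_series`.
#' @param config a [gate_config()].
#' @return a `frame_selection` with per-removal filter and pass provenance.
#' @export
gate_series <- function(series, config) {
  stopifnot(inherits(config, "gate_config"))
  sel1 <- gate_pass(series, config, pass = 1L)
  if (config$passes == 1L) return(sel1)
  kept1 <- restrict_series(series, series$origin_indices %in% sel1$kept)
  sel2 <- gate_pass(kept1, config, pass = 2L)
  new_selection(sel2$kept, c(sel1$removed, sel2$removed),
                rbind(sel1$reason, sel2$reason))
}

#' Score and gate a stack end to end
#'
#' Scores the stack on `channel` under `policy`, applies the configured
#' filters, and — for `passes = 2` with rescoring — recomputes scores on
#' the retained stack before the second pass, so rolling references are no
#' longer contaminated by the artifact frames removed in pass 1.
#'
#' @param stack a `frame_stack`.
#' @param channel reference channel label.
#' @param policy a [reference_policy()].
#' @param config a [gate_config()].
#' @return list with `selection` (a `frame_selection`), `series` (the
#'   pass-1 `score_series`) and `stack` (the gated `frame_stack`).
#' @export
gate_stack <- function(stack, channel = "red", policy = reference_policy(),
                       config = gate_config()) {
  stopifnot(inherits(stack, "frame_stack"), inherits(config, "gate_config"))
  series <- score_stack(stack, channel, policy)
  rescore <- config$rescore_between_passes
  if (is.null(rescore)) rescore <- policy$mode == "rfg"
  if (config$passes == 1L || !rescore) {
    sel <- gate_series(series, config)
    return(list(selection = sel, series = series,
                stack = apply_selection(stack, sel)))
  }
  sel1 <- gate_pass(series, config, pass = 1L)
  kept_stack <- apply_selection(stack, sel1)
  series2 <- score_stack(kept_stack, channel, policy)
  sel2 <- gate_pass(series2, config, pass = 2L)
  sel <- new_selection(sel2$kept, c(sel1$removed, sel2$removed),
                       rbind(sel1$reason, sel2$reason))
  list(selection = sel, series = series, stack = apply_selection(stack, sel))
}

#' Double filtering: two passes of the same filter
#'
#' Convenience wrapper around [gate_stack()] with `passes = 2`; exists
#' because a single relative-maximum pass removes at most one frame per
#' group and therefore cannot eliminate two consecutive distorted frames.
#'
#' @inheritParams gate_stack
#' @return as [gate_stack()].
#' @export
double_filter <- function(stack, channel = "red",
                          policy = reference_policy(), config) {
  stopifnot(inherits(config, "gate_config"))
  if (config$passes != 2L) stop("double_filter requires config with passes = 2")
  gate_stack(stack, channel, policy, config)
}

#' Apply a frame selection to a stack
#'
#' Returns a new stack containing the kept frames in temporal order, with
#' origin indices preserved from the input (this is what keeps timestamps
#' accurate after removal). Applying the same selection twice is a no-op.
#'
#' @param stack a `frame_stack`.
#' @param sel a `frame_selection` whose indices are a subset of
#'   `stack$origin_indices`.
#' @return a `frame_stack` of the kept frames.
#' @export
apply_selection <- function(stack, sel) {
  stopifnot(inherits(stack, "frame_stack"), inherits(sel, "frame_selection"))
  if (!all(sel$kept %in% stack$origin_indices))
    stop("selection refers to unknown origin indices")
  if (!all(stack$origin_indices %in% c(sel$kept, sel$removed)))
    stop("stack holds frames the selection does not cover")
  subset_frames(stack, which(stack$origin_indices %in% sel$kept))
}

#' Compare a selection against planted ground truth
#'
#' @param sel a `frame_selection`.
#' @param truth an `artifact_truth` object from [generate_scene()] (or any
#'   list with a `frames` data frame holding `origin_index` and `label`).
#' @return list of metrics: `artifact_rate_before` (fraction of frames with
#'   a minor or major artifact), `residual_artifact_rate` (artifact
#'   fraction among kept frames), `recall` (artifacts removed / artifacts),
#'   `false_positive_rate` (good frames removed / good frames), plus raw
#'   counts.
#' @export
evaluate_gating <- function(sel, truth) {
  stopifnot(inherits(sel, "frame_selection"))
  tf <- truth$frames
  all_idx <- sort(c(sel$kept, sel$removed))
  if (!setequal(tf$origin_index, all_idx))
    stop("ground truth does not cover the selection's origin indices")
  lab <- tf$label[match(all_idx, tf$origin_index)]
  is_art <- lab != "good"
  kept_mask <- all_idx %in% sel$kept
  n_art <- sum(is_art)
  n_good <- sum(!is_art)
  kept_art <- sum(is_art & kept_mask)
  removed_art <- sum(is_art & !kept_mask)
  removed_good <- sum(!is_art & !kept_mask)
  list(
    n_frames = length(all_idx),
    n_artifacts = n_art,
    n_kept = sum(kept_mask),
    artifact_rate_before = n_art / length(all_idx),
    residual_artifact_rate = if (sum(kept_mask) > 0L)
      kept_art / sum(kept_mask) else 0,
    recall = if (n_art > 0L) removed_art / n_art else NA_real_,
    false_positive_rate = if (n_good > 0L) removed_good / n_good else NA_real_)
}

#' Export a selection as a tidy table
#'
#' @param sel a `frame_selection`.
#' @return data frame with columns `origin_index`, `status`
#'   (`"kept"`/`"removed"`), `filter`, `pass` (NA for kept frames), ordered
#'   by origin index.
#' @export
selection_table <- function(sel) {
  stopifnot(inherits(sel, "frame_selection"))
  all_idx <- sort(c(sel$kept, sel$removed))
  df <- data.frame(origin_index = all_idx,
                   status = ifelse(all_idx %in% sel$kept, "kept", "removed"),
                   filter = NA_character_, pass = NA_integer_)
  if (nrow(sel$reason) > 0L) {
    m <- match(df$origin_index, sel$reason$origin_index)
    df$filter <- sel$reason$filter[m]
    df$pass <- sel$reason$pass[m]
  }
  df
}
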
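#' Reference policy for dissimilarity scoring
#'
#' Scores are computed against either one user-chosen frame
#' (`mode = "single"`) or a rolling reference rebuilt for every frame
#' (`mode = "rfg"`, reference frame generation): the average intensity
#' projection of the window of `window` adjacent frames centred on the frame
#' being scored. Rolling references track slow baseline drift, so the score
#' trace stays flat where a single fixed reference would ramp up with
#' distance from the reference frame.
#'
#' @param mode `"single"` or `"rfg"`.
#' @param single_index 0-based origin-free positional index of the reference
#'   frame (mode `"single"`).
#' @param window odd window length `>= 3` (mode `"rfg"`); sensible values
#'   run from 5 to 30 frames, default 15.
#' @return an object of class `reference_policy`.
#' @export
reference_policy <- function(mode = c("rfg", "single"), single_index = 0L,
                             window = 15L) {
  mode <- match.arg(mode)
  if (mode == "rfg") {
    window <- as.integer(window)
    if (length(window) != 1L || is.na(window) || window < 3L)
      stop("rfg window must be an odd integer >= 3")
    if (window %% 2L == 0L)
      stop("rfg window must be odd, got ", window)
  } else {
    single_index <- as.integer(single_index)
    if (length(single_index) != 1L || is.na(single_index) || single_index < 0L)
      stop("single_index must be a non-negative 0-based frame position")
  }
  structure(list(mode = mode, single_index = single_index, window = window),
            class = "reference_policy")
}

check_policy <- function(policy, T) {
  stopifnot(inherits(policy, "reference_policy"))
  if (policy$mode == "single" && policy$single_index >= T)
    stop("single_index ", policy$single_index,
         " out of range for a ", T, "-frame stack")
  if (policy$mode == "rfg" && policy$window > T)
    stop("rfg window ", policy$window, " exceeds stack length ", T)
  invisible(policy)
}

#' Square-difference dissimilarity score between two frames
#'
#' The per-frame artifact statistic: the mean over pixels of the squared
#' intensity difference between a frame and its reference, computed in real
#' arithmetic (no 8-bit saturation). Identical frames score exactly 0;
#' normalising by pixel count makes scores comparable across resolutions.
#'
#' @param frame,reference numeric matrices of identical dimension
#'   (single channel).
#' @return a single non-negative number.
#' @export
ssd_score <- function(frame, reference) {
  if (!identical(dim(frame), dim(reference)))
    stop("frame and reference dimensions differ")
  mean((as.numeric(frame) - as.numeric(reference))^2)
}

#' Build the reference frame for one scored frame
#'
#' `mode = "single"`: the designated frame itself. `mode = "rfg"`: the
#' arithmetic mean of the window of frames centred on position `t`
#' (including frame `t`), truncated at the stack boundaries rather than
#' padded.
#'
#' @param stack a single-channel `frame_stack`.
#' @param policy a [reference_policy()].
#' @param t 1-based positional index of the frame being scored.
#' @return a real-valued `H x W` matrix.
#' @export
build_reference <- function(stack, policy, t) {
  stopifnot(inherits(stack, "frame_stack"))
  d <- dim(stack$frames)
  if (d[3L] != 1L) stop("build_reference requires a single-channel stack")
  check_policy(policy, d[4L])
  if (t < 1L || t > d[4L]) stop("frame position out of range")
  if (policy$mode == "single")
    return(matrix(stack$frames[, , 1L, policy$single_index + 1L],
                  d[1L], d[2L]))
  h <- (policy$window - 1L) %/% 2L
  lo <- max(1L, t - h)
  hi <- min(d[4L], t + h)
  win <- stack$frames[, , 1L, lo:hi, drop = FALSE]
  matrix(rowMeans(matrix(win, d[1L] * d[2L], hi - lo + 1L)), d[1L], d[2L])
}

#' Score every frame of a stack on its reference channel
#'
#' For each frame, builds its reference under `policy` on the named channel
#' only and records the square-difference score. Rolling-window means are
#' computed with temporal cumulative sums, so scoring is linear in `T`.
#'
#' @param stack a `frame_stack`.
#' @param channel label of the reference channel (the temporally stable
#'   structure, e.g. vessels). Default `"red"`.
#' @param policy a [reference_policy()].
#' @return an object of class `score_series`: list with `scores` (length
#'   `T`, aligned to `origin_indices`), `origin_indices`, `policy`,
#'   `channel`.
#' @export
score_stack <- function(stack, channel = "red", policy = reference_policy()) {
  stopifnot(inherits(stack, "frame_stack"))
  ch <- get_channel(stack, channel)   # H x W x T
  d <- dim(ch)
  T <- d[3L]
  check_policy(policy, T)
  px <- matrix(ch, d[1L] * d[2L], T)  # pixels x T
  if (policy$mode == "single") {
    ref <- px[, policy$single_index + 1L]
    scores <- colMeans((px - ref)^2)
  } else {
    h <- (policy$window - 1L) %/% 2L
    cs <- cbind(0, t(apply(px, 1L, cumsum)))  # pixels x (T+1) prefix sums
    scores <- numeric(T)
    for (t in seq_len(T)) {
      lo <- max(1L, t - h)
      hi <- min(T, t + h)
      ref <- (cs[, hi + 1L] - cs[, lo]) / (hi - lo + 1L)
      scores[t] <- mean((px[, t] - ref)^2)
    }
  }
  structure(list(scores = as.numeric(scores),
                 origin_indices = stack$origin_indices,
                 policy = policy, channel = channel),
            class = "score_series")
}

#' @export
print.score_series <- function(x, ...) {
  cat(sprintf(
    "<score_series> %d frames, channel '%s', mode %s%s\n",
    length(x$scores), x$channel, x$policy$mode,
    if (x$policy$mode == "rfg") sprintf(" (window %d)", x$policy$window)
    else sprintf(" (reference frame %d)", x$policy$single_index)))
  cat(sprintf("  score range [%.4g, %.4g], median %.4g\n",
              min(x$scores), max(x$scores), stats::median(x$scores)))
  invisible(x)
}

#' Score trace and frequency distribution tables
#'
#' Produces the two standard diagnostic tables: the per-frame score trace
#' (for spotting local maxima = artifact frames) and the binned relative
#' frequency distribution of scores.
#'
#' @param series a `score_series`.
#' @param bins number of equal-width histogram bins (default 50).
#' @return list with data frames `trace` (`origin_index`, `score`) and
#'   `histogram` (`bin_left`, `bin_right`, `relative_frequency`; frequencies
#'   sum to 1).
#' @export
score_report <- function(series, bins = 50L) {
  stopifnot(inherits(series, "score_series"))
  s <- series$scores
  if (length(s) == 0L) stop("empty score series")
  bins <- as.integer(bins)
  if (bins < 1L) stop("bins must be >= 1")
  trace <- data.frame(origin_index = series$origin_indices, score = s)
  lo <- min(s)
  hi <- max(s)
  if (hi == lo) hi <- lo + 1  # degenerate all-equal series: one occupied bin
  breaks <- seq(lo, hi, length.out = bins + 1L)
  counts <- tabulate(pmin(findInterval(s, breaks, rightmost.closed = TRUE),
                          bins), nbins = bins)
  hist <- data.frame(bin_left = breaks[-(bins + 1L)],
                     bin_right = breaks[-1L],
                     relative_frequency = counts / length(s))
  list(trace = trace, histogram = hist)
}
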
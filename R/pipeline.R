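#' Validate and complete a pipeline configuration
#'
#' Checks a raw configuration list (typically parsed from YAML/JSON)
#' against the pipeline's invariants, fills documented defaults, and
#' reports *all* violations at once; nothing is partially applied.
#'
#' Defaults: rolling-reference scoring with a 15-frame window, percentile
#' cutoff 60 (the demonstrated headline configuration), neighbor filter
#' off, single pass, alignment off, no enhancement, no annotation.
#'
#' @param config named list; recognized fields: `input`, `layout`,
#'   `metadata`, `reference_channel`, `scoring` (list: `mode`,
#'   `single_index`, `window`), `gating` (list: `percentile`, `neighbors`,
#'   `passes`) or `gating: false` to disable, `alignment` (`"off"` or a
#'   transform kind), `enhancement` (ordered list of stages, each a list
#'   with `stage` = `"subtract"`, `"project"` or `"kalman"` plus its
#'   parameters), `annotation` (list: `timestamp`, `scale_bar_um`),
#'   `output_dir`, `seed`.
#' @return the completed configuration (class `pipeline_config`), or an
#'   error listing every violated field.
#' @export
validate_config <- function(config) {
  errors <- character(0)
  note <- function(msg) errors <<- c(errors, msg)
  cfg <- config

  if (is.null(cfg$input)) note("input: an input stack path is required")
  if (is.null(cfg$layout)) cfg$layout <- "rgb"
  if (!cfg$layout %in% c("rgb", "gray"))
    note("layout: must be 'rgb' or 'gray'")
  if (is.null(cfg$reference_channel)) cfg$reference_channel <- "red"

  sc <- if (is.null(cfg$scoring)) list() else cfg$scoring
  if (is.null(sc$mode)) sc$mode <- "rfg"
  if (!sc$mode %in% c("rfg", "single"))
    note("scoring.mode: must be 'rfg' or 'single'")
  else if (sc$mode == "rfg") {
    if (is.null(sc$window)) sc$window <- 15L
    sc$window <- as.integer(sc$window)
    if (is.na(sc$window) || sc$window < 3L)
      note("scoring.window: must be an odd integer >= 3")
    else if (sc$window %% 2L == 0L)
      note("scoring.window: must be odd (window parity rule)")
  } else {
    if (is.null(sc$single_index)) sc$single_index <- 0L
    sc$single_index <- as.integer(sc$single_index)
    if (is.na(sc$single_index) || sc$single_index < 0L)
      note("scoring.single_index: must be a non-negative frame index")
  }
  cfg$scoring <- sc

  if (is.null(cfg$gating)) cfg$gating <- list()
  if (!identical(cfg$gating, FALSE)) {
    gt <- cfg$gating
    if (is.null(gt$percentile) && is.null(gt$neighbors)) gt$percentile <- 60
    if (!is.null(gt$percentile) &&
        (!is.numeric(gt$percentile) || gt$percentile <= 0 ||
           gt$percentile > 100))
      note("gating.percentile: percentile_cutoff must lie in (0, 100]")
    if (!is.null(gt$neighbors)) {
      gt$neighbors <- as.integer(gt$neighbors)
      if (is.na(gt$neighbors) || gt$neighbors < 3L ||
          gt$neighbors %% 2L == 0L)
        note("gating.neighbors: must be an odd integer >= 3")
    }
    if (is.null(gt$passes)) gt$passes <- 1L
    if (!gt$passes %in% c(1L, 2L)) note("gating.passes: must be 1 or 2")
    cfg$gating <- gt
  }

  if (is.null(cfg$alignment)) cfg$alignment <- "off"
  if (!cfg$alignment %in% c("off", "translation", "rigid",
                            "scaled_rotation", "affine"))
    note("alignment: must be 'off' or a transform kind")

  if (is.null(cfg$enhancement)) cfg$enhancement <- list()
  for (i in seq_along(cfg$enhancement)) {
    st <- cfg$enhancement[[i]]
    if (is.null(st$stage) ||
        !st$stage %in% c("subtract", "project", "kalman"))
      note(sprintf("enhancement[%d].stage: must be subtract/project/kalman",
                   i))
  }

  if (is.null(cfg$annotation)) cfg$annotation <- list()
  if (is.null(cfg$output_dir)) cfg$output_dir <- "."
  if (is.null(cfg$seed)) cfg$seed <- 1L

  if (length(errors) > 0L)
    stop("invalid pipeline configuration:\n  ",
         paste(errors, collapse = "\n  "))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full artifact-removal pipeline
#'
#' Orchestrates load -> split/score -> gate -> align -> enhance ->
#' annotate -> write. Emits the processed stack, the score trace, the
#' selection table, per-frame transforms (when aligning), gating metrics
#' (when ground truth is supplied) and a provenance record with per-stage
#' frame counts. Any stage failure removes partial outputs and re-raises
#' the error named after its stage.
#'
#' @param config a validated or raw configuration list (see
#'   [validate_config()]); raw lists are validated first.
#' @param truth optional `artifact_truth` for metric computation.
#' @return invisibly, a list with the output paths and the in-memory
#'   results (`stack`, `series`, `selection`, `models`, `metrics`,
#'   `provenance`).
#' @export
run_pipeline <- function(config, truth = NULL) {
  if (!inherits(config, "pipeline_config")) config <- validate_config(config)
  out_dir <- config$output_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  written <- character(0)
  emit <- function(name) {
    p <- file.path(out_dir, name)
    written <<- c(written, p)
    p
  }
  stage <- "load"
  result <- tryCatch({
    set.seed(config$seed)
    stack <- read_stack(config$input, config$layout)
    meta <- if (!is.null(config$metadata)) parse_metadata(config$metadata)
    else NULL
    counts <- list(input = n_frames(stack))

    stage <- "score"
    policy <- if (config$scoring$mode == "rfg")
      reference_policy("rfg", window = config$scoring$window)
    else reference_policy("single",
                          single_index = config$scoring$single_index)
    series <- NULL
    selection <- NULL
    metrics <- NULL
    if (!identical(config$gating, FALSE)) {
      stage <- "gate"
      gcfg <- gate_config(
        percentile_cutoff = config$gating$percentile,
        neighbor_group = config$gating$neighbors,
        passes = config$gating$passes)
      gated <- gate_stack(stack, config$reference_channel, policy, gcfg)
      series <- gated$series
      selection <- gated$selection
      stack <- gated$stack
      counts$kept <- n_frames(stack)
      counts$removed <- length(selection$removed)
      utils::write.csv(score_report(series)$trace, emit("scores.csv"),
                       row.names = FALSE)
      utils::write.csv(selection_table(selection), emit("selection.csv"),
                       row.names = FALSE)
      if (!is.null(truth)) {
        metrics <- evaluate_gating(selection, truth)
        jsonlite::write_json(metrics, emit("metrics.json"),
                             auto_unbox = TRUE, digits = NA)
      }
    } else {
      series <- score_stack(stack, config$reference_channel, policy)
      utils::write.csv(score_report(series)$trace, emit("scores.csv"),
                       row.names = FALSE)
    }

    models <- NULL
    if (config$alignment != "off") {
      stage <- "align"
      aligned <- align_stack(stack, config$reference_channel,
                             config$alignment)
      stack <- aligned$stack
      models <- aligned$models
      utils::write.csv(transform_table(models, stack$origin_indices),
                       emit("transforms.csv"), row.names = FALSE)
    }

    for (st in config$enhancement) {
      stage <- paste0("enhance:", st$stage)
      stack <- switch(
        st$stage,
        subtract = {
          chs <- split_channels(stack)
          tgt <- st$target %||% "green"
          src <- st$source %||% "red"
          chs[[tgt]] <- subtract_channel(chs[[tgt]], chs[[src]],
                                         st$alpha %||% 1)
          merge_channels(chs[[1L]], chs[[2L]], chs[[3L]])
        },
        project = project(stack, projection_config(st$kind %||% "average",
                                                   st$window %||% 2L)),
        kalman = kalman_filter(stack, kalman_params(
          gain = st$gain %||% 0.8, mode = st$mode %||% "fixed",
          rho = st$rho %||% 0.05)))
    }

    if (!is.null(config$annotation$timestamp) &&
        !identical(config$annotation$timestamp, FALSE)) {
      stage <- "annotate"
      if (is.null(meta)) stop("timestamping requires a metadata sidecar")
      ts <- timestamp_overlay(stack, meta, timestamp_spec())
      stack <- ts$stack
      utils::write.csv(ts$sidecar, emit("timestamps.csv"),
                       row.names = FALSE)
    }
    if (!is.null(config$annotation$scale_bar_um)) {
      stage <- "annotate"
      if (is.null(meta)) stop("a scale bar requires a metadata sidecar")
      sb <- scale_bar_overlay(stack, meta, config$annotation$scale_bar_um)
      stack <- sb$stack
    }

    stage <- "write"
    counts$output <- n_frames(stack)
    write_stack(stack, emit("processed.tif"))
    written <- c(written, sidecar_path(file.path(out_dir, "processed.tif")))
    provenance <- list(
      package_version = as.character(utils::packageVersion("ivmclean")),
      config = unclass(config),
      seed = config$seed,
      frame_counts = counts)
    jsonlite::write_json(provenance, emit("provenance.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    list(paths = written, stack = stack, series = series,
         selection = selection, models = models, metrics = metrics,
         provenance = provenance)
  }, error = function(e) {
    unlink(written)
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
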
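# On-disk containers (plain CSV throughout) and run configuration.

#' Write / read a position series
#'
#' Columns: `time_s`, `x_cm` and, for 2D data, `y_cm`.
#' @param position data.frame with `time_s` and `linear_position` (written as
#'   `x_cm`) or `x_cm`/`y_cm` columns.
#' @param path file path.
#' @export
write_positions_csv <- function(position, path) {
  df <- if (!is.null(position$linear_position))
    data.frame(time_s = position$time_s, x_cm = position$linear_position)
  else position
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_positions_csv
#' @export
read_positions_csv <- function(path) read.csv(path)

#' Write / read spike trains (columns `cell_id`, `time_s`)
#'
#' @param spikes a [spike_train_set()].
#' @param path file path.
#' @export
write_spikes_csv <- function(spikes, path) {
  stopifnot(inherits(spikes, "spike_train_set"))
  df <- data.frame(
    cell_id = rep(spikes$cell_ids, lengths(spikes$spike_times)),
    time_s = unlist(spikes$spike_times, use.names = FALSE))
  write.csv(df[order(df$time_s), ], path, row.names = FALSE)
  attr(path, "duration") <- spikes$duration
  invisible(path)
}

#' @rdname write_spikes_csv
#' @param duration event duration in seconds (needed to rebuild the set).
#' @param dt sampling step in seconds.
#' @param cell_ids full roster of cells (silent cells are kept).
#' @export
read_spikes_csv <- function(path, duration, dt = 0.002, cell_ids = NULL) {
  df <- read.csv(path)
  if (is.null(cell_ids)) cell_ids <- sort(unique(df$cell_id))
  spk <- lapply(cell_ids, function(i) df$time_s[df$cell_id == i])
  spike_train_set(spk, duration = duration, dt = dt, cell_ids = cell_ids)
}

#' Write / read marked (clusterless) spikes
#'
#' Columns: `tetrode_id`, `time_s`, `m1`..`m4` (uV).
#' @param marks a [marked_spike_set()].
#' @param path file path.
#' @export
write_marks_csv <- function(marks, path) {
  stopifnot(inherits(marks, "marked_spike_set"))
  rows <- lapply(seq_along(marks$tetrodes), function(i) {
    tt <- marks$tetrodes[[i]]
    if (!length(tt$times)) return(NULL)
    data.frame(tetrode_id = marks$tetrode_ids[i], time_s = tt$times,
               m1 = tt$marks[, 1L], m2 = tt$marks[, 2L],
               m3 = tt$marks[, 3L], m4 = tt$marks[, 4L])
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_marks_csv
#' @param duration duration in seconds.
#' @param dt sampling step in seconds.
#' @export
read_marks_csv <- function(path, duration, dt = 0.002) {
  df <- read.csv(path)
  ids <- sort(unique(df$tetrode_id))
  tets <- lapply(ids, function(i) {
    sub <- df[df$tetrode_id == i, , drop = FALSE]
    o <- order(sub$time_s)
    list(times = sub$time_s[o],
         marks = as.matrix(sub[o, c("m1", "m2", "m3", "m4")]))
  })
  marked_spike_set(tets, duration = duration, dt = dt, tetrode_ids = ids)
}

#' Write / read LFP traces (columns `time_s`, `t1`..`tE`; `fs` in a comment
#' -- the first data column spacing recovers it on read)
#' @param lfp list with `fs`, `time_s`, `traces`.
#' @param path file path.
#' @export
write_lfp_csv <- function(lfp, path) {
  df <- data.frame(time_s = lfp$time_s, lfp$traces)
  names(df) <- c("time_s", paste0("t", seq_len(ncol(lfp$traces))))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_lfp_csv
#' @export
read_lfp_csv <- function(path) {
  df <- read.csv(path)
  list(fs = 1 / stats::median(diff(df$time_s)), time_s = df$time_s,
       traces = as.matrix(df[, -1L, drop = FALSE]))
}

#' Write / read a track graph as node + edge tables in one CSV
#'
#' Rows with `record = "node"` carry `x`, `y`; rows with `record = "edge"`
#' carry `from`, `to`, `arm`.
#' @param track a [track_graph()].
#' @param path file path.
#' @export
write_track_graph_csv <- function(track, path) {
  nodes <- data.frame(record = "node", id = seq_len(nrow(track$nodes)),
                      x = track$nodes$x, y = track$nodes$y,
                      from = NA, to = NA, arm = NA)
  edges <- data.frame(record = "edge", id = seq_len(nrow(track$edges)),
                      x = NA, y = NA, from = track$edges$from,
                      to = track$edges$to, arm = track$edges$arm)
  write.csv(rbind(nodes, edges), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_track_graph_csv
#' @param gap_size layout gap in cm.
#' @param origin origin node id.
#' @export
read_track_graph_csv <- function(path, gap_size = 15, origin = 1L) {
  df <- read.csv(path)
  nodes <- df[df$record == "node", c("x", "y")]
  edges <- df[df$record == "edge", c("from", "to", "arm")]
  track_graph(nodes, edges, gap_size = gap_size, origin = origin)
}

#' Write an event list (columns start_s, end_s, kind, peak_z, n_tetrodes)
#' @param events an `event_list`.
#' @param path file path.
#' @export
write_events_csv <- function(events, path) {
  write.csv(as.data.frame(events), path, row.names = FALSE)
  invisible(path)
}

#' Write a posterior as a long CSV (time_s, dynamic, bin, probability)
#' @param post a `replay_posterior`.
#' @param path file path.
#' @param stage `"acausal"` or `"causal"`.
#' @export
write_posterior_csv <- function(post, path, stage = "acausal") {
  a <- post[[stage]]
  if (is.null(a)) stop_param("posterior stage not available")
  d <- dim(a)
  df <- data.frame(
    time_s = rep(post$time, times = d[2L] * d[3L]),
    dynamic = rep(rep(post$labels, each = d[1L]), times = d[3L]),
    bin = rep(seq_len(d[3L]), each = d[1L] * d[2L]),
    probability = as.vector(a))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Default run configuration
#'
#' All defaults are the model's standard parameter values: 3 cm position
#' bins, 2 ms time bins, 6 cm position / 24 uV mark bandwidths, 5 cm spline
#' knots with L2 0.5, stay probability 0.98, random-walk variance 6 cm^2,
#' classification threshold 0.80, and SWR detection at z = 2 for 15 ms below
#' 4 cm/s.
#'
#' @param ... overrides of the default fields.
#' @return named list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(mode = "demo_replay", seed = 1L,
              bin_size = 3, time_bin = 0.002,
              knot_spacing = 5, l2 = 0.5,
              bw_pos = 6.0, bw_mark = 24.0,
              stay_prob = 0.98, rw_variance = 6.0,
              threshold = 0.80,
              z_thresh = 2, min_dur = 0.015, speed_max = 4,
              n_traversals = 15L, run_speed = 15,
              inputs = list())
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop_param("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  validate_run_config(structure(cfg, class = "run_config"))
}

#' @noRd
validate_run_config <- function(cfg) {
  check_positive(cfg$bin_size, "bin_size")
  check_positive(cfg$time_bin, "time_bin")
  check_positive(cfg$bw_pos, "bw_pos")
  check_positive(cfg$bw_mark, "bw_mark")
  if (cfg$stay_prob <= 0 || cfg$stay_prob > 1)
    stop_param("config field `stay_prob` must be in (0, 1]")
  if (cfg$threshold <= 0.5 || cfg$threshold > 1)
    stop_param("config field `threshold` must be in (0.5, 1]")
  cfg
}

#' Read a YAML run configuration
#'
#' Unspecified fields fall back to the standard defaults of [run_config()].
#'
#' @param path YAML file path.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

#' Run the end-to-end pipeline
#'
#' The `demo_replay` mode reproduces the simulation study end to end: simulate
#' the 19-cell Gaussian place-field population and 15 encoding traversals of
#' the 180 cm track, fit the sorted-spikes encoder, construct the 280 ms
#' three-segment test sequence (60 ms stationary / 190 ms continuous / 30 ms
#' fragmented), decode it with the switching model, classify at the
#' configured threshold, and write every artifact (positions, spikes,
#' posterior, classification, event summary, manifest) to `out_dir`. Reruns
#' with the same config are byte-identical.
#'
#' @param config a `run_config`, or path to a YAML config.
#' @param out_dir output directory (created if missing).
#' @return invisibly, a list with the in-memory results and output paths.
#' @export
run_pipeline <- function(config = run_config(), out_dir = tempfile("run")) {
  if (is.character(config)) config <- read_run_config(config)
  config <- validate_run_config(config)
  if (!identical(config$mode, "demo_replay"))
    stop_param("unknown pipeline mode: ", config$mode)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  bank <- place_field_bank()
  enc <- simulate_encoding_run(bank, n_traversals = config$n_traversals,
                               dt = config$time_bin, speed = config$run_speed,
                               seed = config$seed)
  track <- linear_track(bank$track_length)
  grid <- make_grid_1d(track, bin_size = config$bin_size)
  linpos <- linearized_from_1d(track, enc$position$time_s,
                               enc$position$linear_position,
                               speed = rep(config$run_speed,
                                           nrow(enc$position)))
  encoder <- fit_sorted_encoder(enc$spikes, linpos, grid,
                                knot_spacing = config$knot_spacing,
                                l2 = config$l2)
  seq_spikes <- make_test_sequence(bank, dt = config$time_bin,
                                   seed = config$seed)
  dyn <- build_dynamics_model(grid, stay_prob = config$stay_prob,
                              rw_variance = config$rw_variance)
  post <- decode_replay(seq_spikes, encoder, dyn, dt = config$time_bin)
  marg <- dynamics_marginal(post)
  cls <- classify_dynamics(marg, threshold = config$threshold,
                           time = post$time, dt = post$dt)
  pm <- position_marginal(post)
  summ <- summarize_event(cls, pm, grid, animal_xy = NULL, dt = post$dt)
  paths <- list(
    positions = write_positions_csv(enc$position,
                                    file.path(out_dir, "positions.csv")),
    spikes = write_spikes_csv(enc$spikes, file.path(out_dir, "spikes.csv")),
    sequence = write_spikes_csv(seq_spikes,
                                file.path(out_dir, "test_sequence.csv")),
    posterior = write_posterior_csv(post,
                                    file.path(out_dir, "posterior.csv")),
    classification = file.path(out_dir, "classification.csv"),
    summary = file.path(out_dir, "event_summary.csv"),
    manifest = file.path(out_dir, "manifest.json"))
  seg <- attr(cls, "segments")
  write.csv(seg, paths$classification, row.names = FALSE)
  write.csv(data.frame(category = names(summ$durations_ms),
                       duration_ms = summ$durations_ms,
                       mean_speed = summ$mean_speed,
                       mean_hpd_cm = summ$mean_hpd_by_category_cm),
            paths$summary, row.names = FALSE)
  manifest <- list(config = unclass(config)[setdiff(names(config), "inputs")],
                   config_hash = content_hash(unclass(config)),
                   package_version =
                     as.character(utils::packageVersion("replayssm")),
                   seed = config$seed)
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(list(bank = bank, encoder = encoder, posterior = post,
                 classification = cls, summary = summ, paths = paths,
                 config = config))
}

#' Save / load a fitted encoding model
#'
#' Serializes a [fit_sorted_encoder()] or [fit_clusterless_encoder()] model
#' to a single file (R serialization, version 2) together with a hash of its
#' grid's bin centers; loading verifies the hash against a supplied grid so
#' a model is never decoded against a different discretization. Reloading is
#' bit-exact.
#'
#' @param encoder a fitted encoder.
#' @param path file path (conventionally `.rds`).
#' @export
save_encoder <- function(encoder, path) {
  if (!inherits(encoder, c("sorted_encoder", "clusterless_encoder")))
    stop_param("`encoder` must be a fitted encoding model")
  saveRDS(list(encoder = encoder,
               grid_hash = content_hash(encoder$grid$bin_centers)),
          path, version = 2L)
  invisible(path)
}

#' @rdname save_encoder
#' @param grid optional [make_grid_1d()] grid to verify against the stored
#'   grid hash; mismatches are refused.
#' @export
load_encoder <- function(path, grid = NULL) {
  obj <- readRDS(path)
  if (!is.null(grid) &&
      !identical(obj$grid_hash, content_hash(grid$bin_centers)))
    stop_param("stored encoder was fit on a different position grid")
  obj$encoder
}
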
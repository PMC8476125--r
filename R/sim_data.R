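# Synthetic data generation: Gaussian place-field Poisson encoding runs, the
# three-segment test sequence, constant-speed sweeps, clusterless marks, and
# ripple-bearing LFP. Every generator takes an explicit integer seed.

#' A bank of Gaussian place fields on a linear track
#'
#' Describes the simulated population used throughout: cells with Gaussian
#' spatial tuning curves \eqn{\lambda_i(x) = r \exp(-(x - c_i)^2 / 2\sigma^2)}
#' placed at regular intervals along a track. Defaults correspond to 19 cells
#' with 6 cm field SD (36 cm^2 variance), 15 Hz peak rate, spaced every 10 cm
#' on a 180 cm track.
#'
#' @param n_cells number of cells.
#' @param track_length track length in cm.
#' @param spacing distance between adjacent place-field peaks in cm. Peaks are
#'   placed at `0, spacing, 2*spacing, ...`.
#' @param field_sd Gaussian place-field standard deviation in cm.
#' @param peak_rate peak firing rate in Hz (may be 0 for a silent bank).
#' @return an object of class `place_field_bank`.
#' @examples
#' bank <- place_field_bank()
#' rate_at <- place_field_rates(bank, c(0, 90, 180))
#' @export
place_field_bank <- function(n_cells = 19L, track_length = 180,
                             spacing = 10, field_sd = 6, peak_rate = 15) {
  check_positive(track_length, "track_length")
  check_positive(field_sd, "field_sd")
  check_positive(spacing, "spacing")
  if (!is.numeric(peak_rate) || length(peak_rate) != 1L || peak_rate < 0)
    stop_param("`peak_rate` must be a single non-negative number")
  peaks <- seq(0, by = spacing, length.out = n_cells)
  if (any(peaks > track_length + 1e-9))
    stop_param("place-field peaks fall outside [0, track_length]")
  structure(
    list(n_cells = as.integer(n_cells), peak_locations = peaks,
         field_sd = field_sd, peak_rate = peak_rate,
         track_length = track_length),
    class = "place_field_bank")
}

#' @export
print.place_field_bank <- function(x, ...) {
  cat(sprintf(
    "Place-field bank: %d cells on %g cm track (peaks every %g cm, SD %g cm, peak %g Hz)\n",
    x$n_cells, x$track_length, diff(x$peak_locations[1:2]), x$field_sd,
    x$peak_rate))
  invisible(x)
}

#' Evaluate the bank's rate functions at positions
#'
#' @param bank a [place_field_bank()].
#' @param x positions in cm.
#' @return matrix `length(x)` x `n_cells` of rates in Hz.
#' @export
place_field_rates <- function(bank, x) {
  stopifnot(inherits(bank, "place_field_bank"))
  outer(x, bank$peak_locations,
        function(p, c) bank$peak_rate * exp(-(p - c)^2 / (2 * bank$field_sd^2)))
}

#' Construct a set of spike trains
#'
#' @param spike_times list of numeric vectors (seconds), one per cell; each is
#'   sorted non-negative.
#' @param duration total duration in seconds.
#' @param dt the sampling/bin step in seconds (default 2 ms).
#' @param cell_ids optional cell identifiers.
#' @return object of class `spike_train_set`.
#' @export
spike_train_set <- function(spike_times, duration, dt = 0.002,
                            cell_ids = NULL) {
  check_positive(duration, "duration")
  check_positive(dt, "dt")
  spike_times <- lapply(spike_times, function(v) sort(as.numeric(v)))
  bad <- vapply(spike_times, function(v) length(v) && (any(v < 0) ||
                  any(v > duration + 1e-9)), logical(1))
  if (any(bad)) stop_param("spike times must lie within [0, duration]")
  if (is.null(cell_ids)) cell_ids <- seq_along(spike_times)
  structure(list(spike_times = spike_times, cell_ids = cell_ids,
                 duration = duration, dt = dt),
            class = "spike_train_set")
}

#' @export
print.spike_train_set <- function(x, ...) {
  cat(sprintf("Spike trains: %d cells, %.3f s, %d spikes (dt = %g ms)\n",
              length(x$spike_times), x$duration,
              sum(lengths(x$spike_times)), 1000 * x$dt))
  invisible(x)
}

#' Bin spike trains into counts
#'
#' @param spikes a [spike_train_set()].
#' @param time_edges bin edges in seconds (length T+1); spikes outside the
#'   range are dropped with a warning.
#' @return integer matrix T x n_cells of counts.
#' @export
bin_spike_counts <- function(spikes, time_edges) {
  stopifnot(inherits(spikes, "spike_train_set"))
  n_bin <- length(time_edges) - 1L
  counts <- matrix(0L, n_bin, length(spikes$spike_times))
  dropped <- 0L
  for (i in seq_along(spikes$spike_times)) {
    st <- spikes$spike_times[[i]]
    if (!length(st)) next
    inside <- st >= time_edges[1L] & st <= time_edges[n_bin + 1L]
    dropped <- dropped + sum(!inside)
    idx <- findInterval(st[inside], time_edges, rightmost.closed = TRUE)
    tab <- tabulate(idx, nbins = n_bin)
    counts[, i] <- tab
  }
  if (dropped > 0L)
    warning(sprintf("%d spikes outside the time range were dropped", dropped))
  counts
}

#' Simulate an encoding run: traversals of the track with Poisson spiking
#'
#' The latent position sweeps the track end-to-end `n_traversals` times at a
#' constant speed; per 2 ms bin, each cell's spike count is a Poisson draw
#' with mean \eqn{\lambda_i(x_t)\,dt}.
#'
#' @param bank a [place_field_bank()].
#' @param n_traversals number of end-to-end passes (default 15).
#' @param dt time step in seconds (default 2 ms).
#' @param speed running speed in cm/s (default 15).
#' @param seed integer seed.
#' @return list with `position` (data.frame time_s, linear_position) and
#'   `spikes` (a [spike_train_set()]).
#' @export
simulate_encoding_run <- function(bank, n_traversals = 15L, dt = 0.002,
                                  speed = 15, seed = 1L) {
  stopifnot(inherits(bank, "place_field_bank"))
  check_positive(dt, "dt")
  check_positive(speed, "speed")
  if (n_traversals < 1L) stop_param("`n_traversals` must be >= 1")
  set.seed(as.integer(seed))
  total_t <- bank$track_length * n_traversals / speed
  n_bin <- ceiling(total_t / dt)
  t_mid <- (seq_len(n_bin) - 0.5) * dt
  # triangle wave over [0, track_length]
  phase <- (t_mid * speed) %% (2 * bank$track_length)
  pos <- ifelse(phase <= bank$track_length, phase,
                2 * bank$track_length - phase)
  lam <- place_field_rates(bank, pos)         # n_bin x n_cells, Hz
  counts <- matrix(rpois(length(lam), lam * dt), nrow = n_bin)
  spk <- lapply(seq_len(bank$n_cells), function(i)
    rep(t_mid, counts[, i]))
  list(position = data.frame(time_s = t_mid, linear_position = pos),
       spikes = spike_train_set(spk, duration = n_bin * dt, dt = dt))
}

#' @rdname simulate_encoding_run
#' @param object a [place_field_bank()] (for the `simulate` method).
#' @param nsim number of traversals.
#' @param ... passed to [simulate_encoding_run()].
#' @export
simulate.place_field_bank <- function(object, nsim = 15L, seed = 1L, ...) {
  simulate_encoding_run(object, n_traversals = nsim, seed = seed, ...)
}

#' Construct a deterministic test spiking sequence
#'
#' Builds a spike raster from a list of segments of three kinds: in a
#' `stationary` segment a single cell fires once per time bin; in a
#' `continuous` segment the cells fire in sequential spatial order as the
#' latent position sweeps the remaining track at constant speed; in a
#' `fragmented` segment a uniformly random cell fires each bin. The default
#' three-segment structure (60 ms stationary, 190 ms continuous, 30 ms
#' fragmented) gives a 280 ms event expressing all three movement dynamics.
#'
#' @param bank a [place_field_bank()].
#' @param segments data.frame or list of `(kind, duration_ms)`; durations must
#'   be positive multiples of the 2 ms step.
#' @param dt time step in seconds.
#' @param seed integer seed (used for the fragmented shuffle only).
#' @param stationary_cell index of the cell firing during stationary
#'   segments. The default is an interior cell (peak 50 cm) whose Gaussian
#'   field is fully expressed on the track and well separated from the sweep
#'   onset, so the stationary-to-continuous hand-off is unambiguous; edge
#'   cells have truncated fields and blur the constructed boundary.
#' @return a [spike_train_set()] with attribute `latent_position` (cm per
#'   bin) recording the constructed trajectory.
#' @export
make_test_sequence <- function(bank,
                               segments = data.frame(
                                 kind = c("stationary", "continuous",
                                          "fragmented"),
                                 duration_ms = c(60, 190, 30)),
                               dt = 0.002, seed = 1L, stationary_cell = 6L) {
  stopifnot(inherits(bank, "place_field_bank"))
  if (is.list(segments) && !is.data.frame(segments))
    segments <- do.call(rbind, lapply(segments, function(s)
      data.frame(kind = s[[1L]], duration_ms = as.numeric(s[[2L]]))))
  kinds <- as.character(segments$kind)
  durs <- as.numeric(segments$duration_ms)
  if (!all(kinds %in% c("stationary", "continuous", "fragmented")))
    stop_param("unknown segment kind; use stationary/continuous/fragmented")
  step_ms <- dt * 1000
  if (any(durs <= 0) || any(abs(durs / step_ms - round(durs / step_ms)) > 1e-9))
    stop_param("segment durations must be positive multiples of the time step")
  set.seed(as.integer(seed))
  peaks <- bank$peak_locations
  cur_pos <- peaks[stationary_cell]
  active <- integer(0)
  latent <- numeric(0)
  for (s in seq_along(kinds)) {
    n <- as.integer(round(durs[s] / step_ms))
    if (kinds[s] == "stationary") {
      active <- c(active, rep(stationary_cell, n))
      latent <- c(latent, rep(cur_pos, n))
    } else if (kinds[s] == "continuous") {
      # rapid trajectory spanning the whole track (all cells fire in spatial
      # order), running away from the current position's end
      upward <- cur_pos < bank$track_length / 2
      from <- if (upward) 0 else bank$track_length
      target <- if (upward) bank$track_length else 0
      traj <- from + (target - from) * (seq_len(n) - 0.5) / n
      cells <- vapply(traj, function(p) which.min(abs(peaks - p)), integer(1))
      active <- c(active, cells)
      latent <- c(latent, traj)
      cur_pos <- target
    } else {
      cells <- sample.int(bank$n_cells, n, replace = TRUE)
      active <- c(active, cells)
      latent <- c(latent, peaks[cells])
      cur_pos <- latent[length(latent)]
    }
  }
  n_bin <- length(active)
  t_mid <- (seq_len(n_bin) - 0.5) * dt
  spk <- lapply(seq_len(bank$n_cells), function(i) t_mid[active == i])
  out <- spike_train_set(spk, duration = n_bin * dt, dt = dt)
  attr(out, "latent_position") <- latent
  attr(out, "segments") <- data.frame(kind = kinds, duration_ms = durs)
  out
}

#' Constant-speed spiking sweeps
#'
#' For each requested speed, simulates one linear traversal of the track in
#' which each cell emits exactly one spike at the moment the trajectory
#' crosses its place-field peak.
#'
#' @param bank a [place_field_bank()].
#' @param speeds vector of positive speeds in cm/s.
#' @param dt time step in seconds.
#' @return list of [spike_train_set()], one per speed (named by speed).
#' @export
make_constant_speed_sweep <- function(bank, speeds, dt = 0.002) {
  stopifnot(inherits(bank, "place_field_bank"))
  if (any(!is.finite(speeds)) || any(speeds <= 0))
    stop_param("`speeds` must be positive")
  lapply(setNames(speeds, speeds), function(v) {
    cross <- bank$peak_locations / v
    # whole number of time bins covering the traversal
    duration <- ceiling(max(bank$track_length / v, dt) / dt) * dt
    # clamp the final crossing inside the event
    cross <- pmin(cross, duration - 1e-9)
    spike_train_set(as.list(cross), duration = duration, dt = dt)
  })
}

#' Default well-separated cluster mark means
#'
#' Places per-cell mean waveform-amplitude vectors on a coarse 4-D lattice so
#' that any two cells are at least `spacing` microvolts apart (default 3-4x
#' the 24 uV mark bandwidth), resolvable by the clusterless encoder.
#'
#' @param n_cells number of cells.
#' @param base lattice origin in microvolts.
#' @param spacing lattice spacing in microvolts.
#' @return matrix `n_cells` x 4 of mark means (uV).
#' @export
default_mark_means <- function(n_cells, base = 100, spacing = 100) {
  lev <- base + spacing * (0:2)
  grid <- as.matrix(expand.grid(lev, lev, lev, lev))
  dimnames(grid) <- NULL
  if (n_cells > nrow(grid)) stop_param("too many cells for the mark lattice")
  grid[seq_len(n_cells), , drop = FALSE]
}

#' Attach synthetic waveform marks to sorted spikes
#'
#' Gives every spike a 4-channel peak-amplitude mark drawn from an isotropic
#' Gaussian around its cell's mean, then discards cell identity, producing
#' clusterless (multiunit) data on a single synthetic tetrode.
#'
#' @param spikes a [spike_train_set()].
#' @param cluster_mark_means matrix n_cells x 4 of mean marks (uV).
#' @param mark_sd mark noise SD in uV (> 0; use a tiny value for near-exact
#'   cluster means).
#' @param seed integer seed.
#' @return object of class `marked_spike_set` with one tetrode.
#' @export
attach_marks <- function(spikes, cluster_mark_means, mark_sd = 10, seed = 1L) {
  stopifnot(inherits(spikes, "spike_train_set"))
  check_positive(mark_sd, "mark_sd")
  cluster_mark_means <- as.matrix(cluster_mark_means)
  if (nrow(cluster_mark_means) != length(spikes$spike_times) ||
      ncol(cluster_mark_means) != 4L)
    stop_param("`cluster_mark_means` must be an n_cells x 4 matrix")
  set.seed(as.integer(seed))
  times <- unlist(spikes$spike_times, use.names = FALSE)
  cells <- rep(seq_along(spikes$spike_times), lengths(spikes$spike_times))
  o <- order(times)
  times <- times[o]; cells <- cells[o]
  marks <- cluster_mark_means[cells, , drop = FALSE] +
    matrix(rnorm(4L * length(times), sd = mark_sd), ncol = 4L)
  dimnames(marks) <- NULL
  marked_spike_set(list(list(times = times, marks = marks)),
                   duration = spikes$duration, dt = spikes$dt)
}

#' Construct a clusterless (marked) spike set
#'
#' @param tetrodes list (one element per tetrode) of lists with `times`
#'   (sorted seconds) and `marks` (matrix n_spikes x 4, uV).
#' @param duration total duration in seconds.
#' @param dt time step in seconds.
#' @param tetrode_ids optional identifiers.
#' @return object of class `marked_spike_set`.
#' @export
marked_spike_set <- function(tetrodes, duration, dt = 0.002,
                             tetrode_ids = NULL) {
  check_positive(duration, "duration")
  for (tt in tetrodes) {
    if (is.unsorted(tt$times)) stop_param("tetrode spike times must be sorted")
    if (length(tt$times) && (!is.matrix(tt$marks) || ncol(tt$marks) != 4L ||
                             nrow(tt$marks) != length(tt$times)))
      stop_param("marks must be an n_spikes x 4 matrix per tetrode")
  }
  if (is.null(tetrode_ids)) tetrode_ids <- seq_along(tetrodes)
  structure(list(tetrodes = tetrodes, tetrode_ids = tetrode_ids,
                 duration = duration, dt = dt),
            class = "marked_spike_set")
}

#' @export
print.marked_spike_set <- function(x, ...) {
  cat(sprintf("Marked spikes: %d tetrodes, %.3f s, %d spikes\n",
              length(x$tetrodes), x$duration,
              sum(vapply(x$tetrodes, function(t) length(t$times), integer(1)))))
  invisible(x)
}

#' Simulate LFP traces carrying sharp-wave-ripple bursts
#'
#' Broadband Gaussian noise plus amplitude-modulated (Hann envelope) ripple
#' band sinusoids in the stated intervals, shared across tetrodes.
#'
#' @param duration total duration in seconds.
#' @param ripple_intervals list of `c(start, end)` pairs or a 2-column matrix
#'   (seconds); must lie within the duration and not overlap.
#' @param ripple_freq ripple frequency in Hz (150-250 band).
#' @param fs sampling rate in Hz (default 1500).
#' @param n_tetrodes number of traces.
#' @param amplitude burst amplitude as a multiple of the noise SD.
#' @param noise_sd broadband noise SD.
#' @param seed integer seed.
#' @return list with `fs`, `time_s`, and `traces` (samples x tetrodes).
#' @export
simulate_lfp_with_ripples <- function(duration, ripple_intervals = list(),
                                      ripple_freq = 200, fs = 1500,
                                      n_tetrodes = 4L, amplitude = 5,
                                      noise_sd = 1, seed = 1L) {
  check_positive(duration, "duration")
  if (ripple_freq < 150 || ripple_freq > 250)
    stop_param("`ripple_freq` must lie in the 150-250 Hz ripple band")
  iv <- if (is.matrix(ripple_intervals)) ripple_intervals else
    do.call(rbind, lapply(ripple_intervals, as.numeric))
  if (!is.null(iv) && nrow(iv)) {
    if (any(iv[, 1L] < 0) || any(iv[, 2L] > duration) ||
        any(iv[, 2L] <= iv[, 1L]))
      stop_param("ripple intervals must be within [0, duration] with end > start")
    o <- order(iv[, 1L]); iv <- iv[o, , drop = FALSE]
    if (nrow(iv) > 1L && any(iv[-1L, 1L] < iv[-nrow(iv), 2L]))
      stop_param("ripple intervals must not overlap")
  }
  set.seed(as.integer(seed))
  n <- round(duration * fs)
  tt <- (seq_len(n) - 1L) / fs
  traces <- matrix(rnorm(n * n_tetrodes, sd = noise_sd), n, n_tetrodes)
  if (!is.null(iv) && nrow(iv)) {
    for (r in seq_len(nrow(iv))) {
      idx <- which(tt >= iv[r, 1L] & tt < iv[r, 2L])
      env <- 0.5 * (1 - cos(2 * pi * seq_along(idx) / (length(idx) + 1L)))
      burst <- amplitude * noise_sd * env * sin(2 * pi * ripple_freq * tt[idx])
      traces[idx, ] <- traces[idx, ] + burst
    }
  }
  list(fs = fs, time_s = tt, traces = traces,
       ripple_intervals = iv)
}
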
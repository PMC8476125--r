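# Candidate event detection: sharp-wave ripples from LFP and high
# multiunit-activity periods, with speed gating and tetrode-participation
# filters.

#' Build an event list data.frame
#' @noRd
event_list <- function(start_s, end_s, kind, peak_z,
                       n_tetrodes = rep(NA_integer_, length(start_s))) {
  out <- data.frame(start_s = start_s, end_s = end_s, kind = kind,
                    peak_z = peak_z, n_tetrodes = n_tetrodes)
  out <- out[order(out$start_s), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("event_list", "data.frame")
  out
}

#' Threshold a z-scored trace into gated, boundary-extended events
#'
#' Core runs require z > z_thresh for at least min_dur and speed < speed_max
#' throughout; each run is then extended on both sides until the trace
#' returns to its session mean (z <= 0), and overlapping extended events are
#' merged.
#' @noRd
detect_from_zscore <- function(z, fs, speed, z_thresh, min_dur, speed_max,
                               kind) {
  n <- length(z)
  if (is.null(speed)) speed <- rep(0, n)
  if (length(speed) == 1L) speed <- rep(speed, n)
  if (length(speed) < n) stop_param("speed series shorter than the trace")
  above <- z > z_thresh
  runs <- rle_runs(above)
  runs <- runs[runs$value == "TRUE", , drop = FALSE]
  keep <- which((runs$end - runs$start + 1L) >= round(min_dur * fs) &
                  vapply(seq_len(nrow(runs)), function(r)
                    all(speed[runs$start[r]:runs$end[r]] < speed_max),
                    logical(1)))
  if (!length(keep))
    return(event_list(numeric(0), numeric(0), character(0), numeric(0)))
  runs <- runs[keep, , drop = FALSE]
  lo <- integer(nrow(runs)); hi <- integer(nrow(runs)); pk <- numeric(nrow(runs))
  for (r in seq_len(nrow(runs))) {
    i <- runs$start[r]
    while (i > 1L && z[i - 1L] > 0) i <- i - 1L
    j <- runs$end[r]
    while (j < n && z[j + 1L] > 0) j <- j + 1L
    lo[r] <- i; hi[r] <- j
    pk[r] <- max(z[runs$start[r]:runs$end[r]])
  }
  # merge overlapping extended events
  o <- order(lo)
  lo <- lo[o]; hi <- hi[o]; pk <- pk[o]
  ml <- lo[1L]; mh <- hi[1L]; mp <- pk[1L]
  out_l <- integer(0); out_h <- integer(0); out_p <- numeric(0)
  for (r in seq_along(lo)[-1L]) {
    if (lo[r] <= mh + 1L) { mh <- max(mh, hi[r]); mp <- max(mp, pk[r]) }
    else { out_l <- c(out_l, ml); out_h <- c(out_h, mh); out_p <- c(out_p, mp)
           ml <- lo[r]; mh <- hi[r]; mp <- pk[r] }
  }
  out_l <- c(out_l, ml); out_h <- c(out_h, mh); out_p <- c(out_p, mp)
  event_list((out_l - 1L) / fs, out_h / fs, rep(kind, length(out_l)), out_p)
}

#' Detect sharp-wave ripples from LFP traces
#'
#' Each trace is bandpass filtered for the ripple band (150-250 Hz) with a
#' zero-phase FIR filter (forward-backward), squared, and summed across
#' tetrodes into a single population trace; this is smoothed with a Gaussian
#' (4 ms SD), square-rooted, and z-scored over the whole recording.
#' Candidate events require the z-score to exceed `z_thresh` for at least
#' `min_dur` while the animal moves slower than `speed_max`; event
#' boundaries are then extended until the population trace returns to its
#' mean, and overlapping events merge.
#'
#' @param lfp list with `fs` and `traces` (samples x tetrodes), as returned
#'   by [simulate_lfp_with_ripples()], or a numeric matrix with `fs` given.
#' @param speed animal speed (cm/s) per LFP sample (a scalar is recycled;
#'   NULL means immobile).
#' @param fs sampling rate in Hz if `lfp` is a bare matrix.
#' @param z_thresh z-score threshold (default 2).
#' @param min_dur minimum supra-threshold duration in seconds (default 15 ms).
#' @param speed_max immobility speed ceiling in cm/s (default 4).
#' @param smooth_sd Gaussian smoothing SD in seconds (default 4 ms).
#' @param filter_order FIR filter order (default 80).
#' @return an `event_list` data.frame (`start_s`, `end_s`, `kind`, `peak_z`,
#'   `n_tetrodes`).
#' @export
detect_swr <- function(lfp, speed = NULL, fs = NULL, z_thresh = 2,
                       min_dur = 0.015, speed_max = 4, smooth_sd = 0.004,
                       filter_order = 80L) {
  if (is.list(lfp) && !is.null(lfp$traces)) { fs <- lfp$fs; traces <- lfp$traces }
  else { traces <- as.matrix(lfp) }
  if (is.null(fs)) stop_param("sampling rate `fs` required")
  if (is.null(dim(traces)) || ncol(traces) < 1L)
    stop_param("need at least one LFP trace")
  if (nrow(traces) <= 3L * filter_order)
    stop_param("trace too short for the ripple filter")
  # plain numeric coefficients so filtfilt(b, a, x) hits the default method
  b <- as.numeric(signal::fir1(filter_order, c(150, 250) / (fs / 2),
                               type = "pass"))
  pop <- rowSums(apply(traces, 2L, function(tr)
    signal::filtfilt(b, 1, tr)^2))
  pop <- sqrt(pmax(gaussian_smooth(pop, sd = smooth_sd * fs), 0))
  z <- (pop - mean(pop)) / sd(pop)
  detect_from_zscore(z, fs, speed, z_thresh, min_dur, speed_max, "swr")
}

#' Detect periods of high multiunit activity
#'
#' Z-scores the population multiunit rate over the whole recording and finds
#' immobility periods where it exceeds `z_thresh` for at least `min_dur`,
#' extended to the mean crossings, exactly as for SWR detection but without
#' the ripple filter bank.
#'
#' @param mua_rate population multiunit spike rate series (Hz).
#' @param fs sampling rate of the series in Hz.
#' @param speed animal speed per sample (scalar recycled; NULL = immobile).
#' @param z_thresh z-score threshold (default 2).
#' @param min_dur minimum duration in seconds (default 15 ms).
#' @param speed_max immobility ceiling in cm/s (default 4).
#' @param smooth_sd optional Gaussian smoothing SD in seconds (default 0, no
#'   smoothing).
#' @return an `event_list` data.frame.
#' @export
detect_high_mua <- function(mua_rate, fs, speed = NULL, z_thresh = 2,
                            min_dur = 0.015, speed_max = 4, smooth_sd = 0) {
  mua_rate <- as.numeric(mua_rate)
  if (smooth_sd > 0) mua_rate <- gaussian_smooth(mua_rate, sd = smooth_sd * fs)
  s <- sd(mua_rate)
  if (s == 0) {
    return(event_list(numeric(0), numeric(0), character(0), numeric(0)))
  }
  z <- (mua_rate - mean(mua_rate)) / s
  detect_from_zscore(z, fs, speed, z_thresh, min_dur, speed_max, "mua")
}

#' Keep only events with sufficient tetrode participation
#'
#' Counts the tetrodes (for [marked_spike_set()] input) or units (for
#' [spike_train_set()] input) with at least one spike inside each event and
#' drops events below `min_tetrodes`.
#'
#' @param events an `event_list`.
#' @param spikes a [marked_spike_set()] or [spike_train_set()].
#' @param min_tetrodes minimum participating tetrode count (default 2).
#' @return the filtered `event_list` with `n_tetrodes` filled in.
#' @export
filter_events <- function(events, spikes, min_tetrodes = 2L) {
  stopifnot(inherits(events, "event_list"))
  times <- if (inherits(spikes, "marked_spike_set"))
    lapply(spikes$tetrodes, `[[`, "times")
  else if (inherits(spikes, "spike_train_set")) spikes$spike_times
  else stop_param("`spikes` must be a marked_spike_set or spike_train_set")
  if (!nrow(events)) return(events)
  events$n_tetrodes <- vapply(seq_len(nrow(events)), function(r)
    sum(vapply(times, function(tt)
      any(tt >= events$start_s[r] & tt <= events$end_s[r]), logical(1))),
    integer(1))
  out <- events[events$n_tetrodes >= min_tetrodes, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("event_list", "data.frame")
  out
}
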
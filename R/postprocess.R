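# Posterior summaries: dynamics and position marginals, five-category speed
# classification, highest-posterior-density regions, MAP positions, replay
# speed, and per-event summaries.

CATEGORY_LABELS <- c("stationary", "stationary-continuous-mixture",
                     "continuous", "fragmented-continuous-mixture",
                     "fragmented", "unclassified")
COHERENT_CATEGORIES <- c("stationary", "stationary-continuous-mixture",
                         "continuous")
INCOHERENT_CATEGORIES <- c("fragmented-continuous-mixture", "fragmented")

#' Probability of each movement dynamic over time
#'
#' Integrates position out of the joint posterior (Riemann sum over grid
#' bins).
#'
#' @param post a `replay_posterior`.
#' @param stage `"acausal"` (default) or `"causal"`.
#' @return matrix n_time x n_dynamics; rows sum to 1.
#' @export
dynamics_marginal <- function(post, stage = c("acausal", "causal")) {
  stopifnot(inherits(post, "replay_posterior"))
  stage <- match.arg(stage)
  a <- post[[stage]]
  if (is.null(a)) stop_param("run acausal_smoother() first")
  out <- apply(a, c(1L, 2L), sum)
  colnames(out) <- post$labels
  out
}

#' Posterior probability of position over time
#'
#' Marginalizes the joint posterior over the movement dynamics.
#'
#' @inheritParams dynamics_marginal
#' @return matrix n_time x n_bins; rows sum to 1.
#' @export
position_marginal <- function(post, stage = c("acausal", "causal")) {
  stopifnot(inherits(post, "replay_posterior"))
  stage <- match.arg(stage)
  a <- post[[stage]]
  if (is.null(a)) stop_param("run acausal_smoother() first")
  apply(a, c(1L, 3L), sum)
}

#' Classify each time bin into one of five speed categories
#'
#' A bin is labeled `stationary`, `continuous`, or `fragmented` when that
#' dynamic's probability exceeds the threshold; otherwise
#' `stationary-continuous-mixture` or `fragmented-continuous-mixture` when
#' the corresponding pair sum exceeds it (mixtures always pair continuous
#' with one other dynamic); otherwise `unclassified`. Individual labels take
#' precedence over mixtures; if both mixtures clear the threshold the larger
#' sum wins (ties to the stationary mixture). "Exceeds" is strict (`>`).
#'
#' @param marg n_time x 3 dynamics marginal with columns stationary,
#'   continuous, fragmented (see [dynamics_marginal()]).
#' @param threshold classification threshold in (0.5, 1] (default 0.80).
#' @param time optional bin-center times in seconds.
#' @param dt bin width in seconds (default 2 ms), used for segment durations.
#' @return data.frame of class `replay_classification` with columns `time`,
#'   `label` (factor over the five categories plus unclassified), and
#'   attribute `segments`: contiguous same-label runs with start/end times
#'   and durations in ms.
#' @export
classify_dynamics <- function(marg, threshold = 0.80, time = NULL,
                              dt = 0.002) {
  marg <- as.matrix(marg)
  if (ncol(marg) != 3L)
    stop_param("classification needs the three standard dynamics")
  if (!is.numeric(threshold) || threshold <= 0.5 || threshold > 1)
    stop_param("`threshold` must lie in (0.5, 1]")
  if (max(abs(rowSums(marg) - 1)) > 1e-6)
    stop_param("dynamics marginal rows must sum to 1")
  ps <- marg[, 1L]; pc <- marg[, 2L]; pf <- marg[, 3L]
  scm <- ps + pc; fcm <- pf + pc
  label <- rep("unclassified", nrow(marg))
  label[scm > threshold & scm >= fcm] <- "stationary-continuous-mixture"
  label[fcm > threshold & fcm > scm] <- "fragmented-continuous-mixture"
  label[ps > threshold] <- "stationary"
  label[pc > threshold] <- "continuous"
  label[pf > threshold] <- "fragmented"
  if (is.null(time)) time <- (seq_len(nrow(marg)) - 0.5) * dt
  out <- data.frame(time = time,
                    label = factor(label, levels = CATEGORY_LABELS))
  class(out) <- c("replay_classification", "data.frame")
  runs <- rle_runs(label)
  segments <- data.frame(
    category = runs$value,
    start_s = time[runs$start] - dt / 2,
    end_s = time[runs$end] + dt / 2,
    duration_ms = (runs$end - runs$start + 1L) * dt * 1000)
  attr(out, "segments") <- segments
  attr(out, "threshold") <- threshold
  attr(out, "dt") <- dt
  out
}

#' @export
print.replay_classification <- function(x, ...) {
  seg <- attr(x, "segments")
  cat(sprintf("Replay classification: %d bins, threshold %g\n",
              nrow(x), attr(x, "threshold")))
  print(seg, row.names = FALSE)
  invisible(x)
}

#' Highest-posterior-density region per time bin
#'
#' Finds, per row of the position marginal, the maximum threshold h such
#' that bins with probability above h hold at least `coverage` of the mass
#' (equivalently the smallest set of highest-probability bins reaching the
#' coverage; ties broken by bin index). The region size is the summed width
#' of the member bins, in cm.
#'
#' @param marg_pos n_time x n_bins position marginal (rows sum to 1).
#' @param coverage HPD mass (default 0.95).
#' @param widths bin widths in cm (default: equal 3 cm bins).
#' @return list with `size` (cm per time bin), `members` (logical n_time x
#'   n_bins), `threshold` (h per time bin).
#' @export
hpd_region <- function(marg_pos, coverage = 0.95,
                       widths = rep(3, ncol(marg_pos))) {
  marg_pos <- as.matrix(marg_pos)
  if (coverage <= 0 || coverage > 1) stop_param("`coverage` must be in (0, 1]")
  n_time <- nrow(marg_pos); n_bins <- ncol(marg_pos)
  members <- matrix(FALSE, n_time, n_bins)
  size <- numeric(n_time); h <- numeric(n_time)
  for (k in seq_len(n_time)) {
    p <- marg_pos[k, ]
    o <- order(-p, seq_len(n_bins))          # descending, ties by bin index
    cum <- cumsum(p[o])
    m <- which(cum >= coverage - 1e-12)[1L]
    if (is.na(m)) m <- n_bins
    members[k, o[seq_len(m)]] <- TRUE
    size[k] <- sum(widths[o[seq_len(m)]])
    h[k] <- p[o[m]]
  }
  list(size = size, members = members, threshold = h)
}

#' Maximum a posteriori position per time bin
#'
#' @param marg_pos n_time x n_bins position marginal.
#' @param centers bin centers in cm.
#' @return data.frame `bin` (index, ties to the lowest index) and `position`
#'   (cm).
#' @export
map_position <- function(marg_pos, centers) {
  marg_pos <- as.matrix(marg_pos)
  bin <- apply(marg_pos, 1L, which.max)
  data.frame(bin = bin, position = centers[bin])
}

#' Estimate replay speed from the MAP position track
#'
#' Computes the first derivative of the MAP position by central differences
#' (one-sided at the boundaries), smooths it with a small Gaussian (default
#' SD 2.5 ms), and takes the absolute value. If a classification is
#' supplied, returns the per-segment mean speed, excluding segments shorter
#' than `min_duration` (20 ms by default; at 3 cm bins and 2 ms steps slower
#' speeds cannot be resolved within shorter windows).
#'
#' @param map_track MAP positions in cm (see [map_position()]).
#' @param dt time step in seconds (default 2 ms).
#' @param smooth_sd Gaussian smoothing SD in seconds (default 2.5 ms).
#' @param classification optional [classify_dynamics()] result.
#' @param min_duration minimum analyzable segment duration in seconds.
#' @return if `classification` is NULL, the smoothed absolute speed series
#'   (cm/s); otherwise the segment table with a `mean_speed` column (NA for
#'   segments shorter than `min_duration`).
#' @export
estimate_speed <- function(map_track, dt = 0.002, smooth_sd = 0.0025,
                           classification = NULL, min_duration = 0.020) {
  speed <- abs(gaussian_smooth(gradient1d(map_track, dt), sd = smooth_sd / dt))
  if (is.null(classification)) return(speed)
  seg <- attr(classification, "segments")
  time <- classification$time
  seg$mean_speed <- vapply(seq_len(nrow(seg)), function(r) {
    idx <- which(time > seg$start_s[r] & time < seg$end_s[r])
    if (length(idx) * dt < min_duration || length(idx) < 2L) return(NA_real_)
    mean(speed[idx])
  }, numeric(1))
  seg
}

#' Summarize a decoded event
#'
#' Collects per-category durations, mean speeds, mean distances from the
#' animal, mean HPD region size, and the spatial-content flags: an event is
#' spatially coherent if it contains stationary, stationary-continuous
#' mixture, or continuous periods, spatially incoherent if it contains
#' fragmented or fragmented-continuous mixture periods, and non-local
#' stationary if a stationary-classified bin decodes at least
#' `non_local_distance` cm from the animal.
#'
#' @param classification a [classify_dynamics()] result.
#' @param marg_pos the position marginal used for MAP/HPD summaries.
#' @param grid the 1D [make_grid_1d()] grid.
#' @param animal_xy optional animal 2D position (cm); when absent, distance
#'   fields are NA and flagged absent.
#' @param dt time step in seconds.
#' @param non_local_distance non-local threshold in cm (default 30).
#' @param hpd_coverage HPD mass (default 0.95).
#' @return object of class `event_summary`: a list with `categories`,
#'   `durations_ms`, `mean_speed`, `mean_distance_cm`, `mean_hpd_cm`,
#'   `spatially_coherent`, `spatially_incoherent`, `non_local_stationary`,
#'   `distance_available`.
#' @export
summarize_event <- function(classification, marg_pos, grid, animal_xy = NULL,
                            dt = 0.002, non_local_distance = 30,
                            hpd_coverage = 0.95) {
  stopifnot(inherits(classification, "replay_classification"))
  lab <- as.character(classification$label)
  durations <- vapply(setNames(CATEGORY_LABELS, CATEGORY_LABELS),
                      function(cc) sum(lab == cc) * dt * 1000, numeric(1))
  mp <- map_position(marg_pos, grid$bin_centers)
  speed <- estimate_speed(mp$position, dt = dt)
  hpd <- hpd_region(marg_pos, coverage = hpd_coverage, widths = grid$widths)
  dist <- rep(NA_real_, nrow(mp))
  dist_available <- !is.null(animal_xy)
  if (dist_available)
    dist <- distance_from_animal(grid, mp$bin, animal_xy)
  agg <- function(v) vapply(setNames(CATEGORY_LABELS, CATEGORY_LABELS),
                            function(cc) if (any(lab == cc))
                              mean(v[lab == cc]) else NA_real_, numeric(1))
  present <- unique(lab[lab != "unclassified"])
  structure(list(
    categories = present,
    durations_ms = durations,
    mean_speed = agg(speed),
    mean_distance_cm = agg(dist),
    mean_hpd_cm = mean(hpd$size),
    mean_hpd_by_category_cm = agg(hpd$size),
    spatially_coherent = any(present %in% COHERENT_CATEGORIES),
    spatially_incoherent = any(present %in% INCOHERENT_CATEGORIES),
    non_local_stationary = dist_available &&
      any(lab == "stationary" & dist >= non_local_distance, na.rm = TRUE),
    distance_available = dist_available,
    event_duration_ms = nrow(mp) * dt * 1000), class = "event_summary")
}

#' @export
print.event_summary <- function(x, ...) {
  cat(sprintf("Event summary (%.0f ms): %s\n", x$event_duration_ms,
              paste(x$categories, collapse = ", ")))
  cat(sprintf("  coherent %s | incoherent %s | non-local stationary %s | mean HPD %.1f cm\n",
              x$spatially_coherent, x$spatially_incoherent,
              x$non_local_stationary, x$mean_hpd_cm))
  invisible(x)
}
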
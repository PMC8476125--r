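# Standard ('Bayesian') decoder baselines: 20 ms posterior with uniform
# prior, Radon-transform line fitting with circular-shuffle significance,
# linear-regression line fitting, MAP speed, and the two encoding-shuffle
# controls.

#' Standard-decoder posterior with a uniform prior
#'
#' Evaluates the (sorted or clusterless) likelihood in wide time bins
#' (20 ms by default) and normalizes against a uniform position prior, with
#' no movement-dynamics prior: the classical independent-bin decoder.
#'
#' @param encoder a fitted [fit_sorted_encoder()] or
#'   [fit_clusterless_encoder()] model.
#' @param data a [spike_train_set()] or [marked_spike_set()] for the event.
#' @param dt bin width in seconds (default 20 ms).
#' @param time_edges optional explicit edges.
#' @return matrix n_time x n_bins of position probabilities (rows sum to 1)
#'   with attributes `time` (bin centers), `dt`, and `centers`.
#' @export
standard_posterior <- function(encoder, data, dt = 0.020, time_edges = NULL) {
  if (is.null(time_edges)) time_edges <- event_time_edges(data$duration, dt)
  lik <- if (inherits(encoder, "sorted_encoder"))
    sorted_likelihood(encoder, data, time_edges)
  else clusterless_likelihood(encoder, data, time_edges)
  w <- encoder$grid$widths
  ll <- lik$loglik + matrix(log(w / sum(w)), nrow(lik$loglik), length(w),
                            byrow = TRUE)
  post <- exp(ll - apply(ll, 1L, max))
  post <- post / rowSums(post)
  attr(post, "time") <- (time_edges[-1L] + head(time_edges, -1L)) / 2
  attr(post, "dt") <- lik$dt
  attr(post, "centers") <- encoder$grid$bin_centers
  post
}

#' Construct a line-fit result
#' @noRd
line_fit <- function(slope, intercept, score, p_value, arm_combination,
                     method) {
  if (!is.na(p_value) && (p_value < 0 || p_value > 1))
    stop_param("p-value outside [0, 1]")
  structure(list(slope = slope, intercept = intercept, score = score,
                 p_value = p_value, arm_combination = arm_combination,
                 method = method), class = "line_fit")
}

#' @export
print.line_fit <- function(x, ...) {
  cat(sprintf("%s fit: slope %.1f cm/s, intercept %.1f cm, score %.4f, p = %s (arms: %s)\n",
              x$method, x$slope, x$intercept, x$score,
              format.pval(x$p_value), x$arm_combination))
  invisible(x)
}

#' Best line through a posterior by dense Radon-style scanning
#' @return list(slope, intercept, score)
#' @noRd
radon_scan <- function(post, t_rel, centers, slopes, intercepts) {
  n_time <- nrow(post)
  n_lines <- length(slopes) * length(intercepts)
  sl <- rep(slopes, times = length(intercepts))
  ic <- rep(intercepts, each = length(slopes))
  # nearest grid bin per (line, time); outside-track points contribute 0
  best <- c(score = -Inf, slope = NA_real_, intercept = NA_real_)
  edges <- c(centers[1L] - (centers[2L] - centers[1L]) / 2,
             (centers[-1L] + centers[-length(centers)]) / 2,
             centers[length(centers)] +
               (centers[length(centers)] - centers[length(centers) - 1L]) / 2)
  scores <- numeric(n_lines)
  for (k in seq_len(n_time)) {
    pos <- ic + sl * t_rel[k]
    bin <- findInterval(pos, edges)
    ok <- bin >= 1L & bin <= length(centers)
    v <- numeric(n_lines)
    v[ok] <- post[k, bin[ok]]
    scores <- scores + v
  }
  scores <- scores / n_time
  i <- which.max(scores)
  list(slope = sl[i], intercept = ic[i], score = scores[i])
}

#' Fit a constant-speed line to a posterior with the Radon transform method
#'
#' Densely samples candidate lines (a grid of slopes and intercepts), scores
#' each by the mean posterior probability along the line, and keeps the
#' maximum. Significance comes from circularly shuffling the posterior of
#' each time bin (independent random offset per bin by default; a common
#' per-shuffle offset behind `shuffle = "common"`) and comparing scores.
#' When arm combinations are given (e.g. center+left vs center+right bins of
#' a W-track), each combination is fitted on its renormalized sub-posterior
#' and the best-scoring combination is returned.
#'
#' @param post posterior matrix from [standard_posterior()].
#' @param n_shuffles number of circular shuffles (default 1000).
#' @param seed integer seed.
#' @param arm_combinations named list of bin-index vectors (default: one
#'   combination with every bin).
#' @param n_slopes number of slopes spanning +/- `max_slope` (default 101,
#'   an odd count so the zero-slope line of a stationary event is in the
#'   scanned family).
#' @param max_slope largest |slope| scanned, cm/s (default 1e4).
#' @param shuffle `"independent"` per-bin offsets or `"common"` offset.
#' @return a `line_fit` (slope cm/s, intercept cm, Radon score, p-value).
#' @export
radon_fit <- function(post, n_shuffles = 1000L, seed = 1L,
                      arm_combinations = NULL, n_slopes = 101L,
                      max_slope = 1e4, shuffle = c("independent", "common")) {
  shuffle <- match.arg(shuffle)
  time <- attr(post, "time"); centers <- attr(post, "centers")
  if (nrow(post) < 2L) stop_param("single-bin events cannot be line-fitted")
  t_rel <- time - mean(time)
  slopes <- seq(-max_slope, max_slope, length.out = n_slopes)
  if (is.null(arm_combinations))
    arm_combinations <- list(all = seq_along(centers))
  set.seed(as.integer(seed))
  best <- NULL
  for (ac in names(arm_combinations)) {
    idx <- arm_combinations[[ac]]
    sub <- post[, idx, drop = FALSE]
    sub <- sub / pmax(rowSums(sub), 1e-300)
    ctr <- centers[idx]
    obs <- radon_scan(sub, t_rel, ctr, slopes, ctr)
    exceed <- 0L
    for (s in seq_len(n_shuffles)) {
      off <- if (shuffle == "independent")
        sample.int(length(idx), nrow(sub), replace = TRUE) - 1L
      else rep(sample.int(length(idx), 1L) - 1L, nrow(sub))
      shuf <- sub
      for (k in seq_len(nrow(sub)))
        if (off[k] > 0L)
          shuf[k, ] <- sub[k, c((off[k] + 1L):length(idx), 1L:off[k])]
      if (radon_scan(shuf, t_rel, ctr, slopes, ctr)$score >= obs$score)
        exceed <- exceed + 1L
    }
    p <- (1 + exceed) / (n_shuffles + 1)
    fit <- line_fit(obs$slope, obs$intercept, obs$score, p, ac, "radon")
    if (is.null(best) || fit$score > best$score) best <- fit
  }
  best
}

#' Fit a line by sampling positions and linear regression
#'
#' Draws `n_samples` positions per time bin from the posterior, regresses
#' position on time by ordinary least squares, and selects the best arm
#' combination by R-squared. Zero-slope (stationary) structure can never be
#' significant under this method's slope test.
#'
#' @inheritParams radon_fit
#' @param n_samples samples per time bin (default 1000).
#' @return a `line_fit` with `score` = R-squared and `p_value` = slope
#'   t-test p (NA, flagged, when the sampled positions are degenerate).
#' @export
linreg_fit <- function(post, n_samples = 1000L, seed = 1L,
                       arm_combinations = NULL) {
  time <- attr(post, "time"); centers <- attr(post, "centers")
  if (nrow(post) < 2L) stop_param("single-bin events cannot be line-fitted")
  if (is.null(arm_combinations))
    arm_combinations <- list(all = seq_along(centers))
  set.seed(as.integer(seed))
  best <- NULL
  for (ac in names(arm_combinations)) {
    idx <- arm_combinations[[ac]]
    sub <- post[, idx, drop = FALSE]
    sub <- sub / pmax(rowSums(sub), 1e-300)
    ctr <- centers[idx]
    xs <- unlist(lapply(seq_len(nrow(sub)), function(k)
      sample(ctr, n_samples, replace = TRUE, prob = sub[k, ])))
    ts <- rep(time, each = n_samples)
    if (stats::var(xs) == 0) {
      fit <- line_fit(0, xs[1L], NA_real_, NA_real_, ac, "linreg")
    } else {
      m <- lm(xs ~ ts)
      sm <- summary(m)
      fit <- line_fit(unname(coef(m)[2L]), unname(coef(m)[1L]),
                      sm$r.squared, unname(sm$coefficients[2L, 4L]),
                      ac, "linreg")
    }
    if (is.null(best) || isTRUE(fit$score > best$score) ||
        (is.na(best$score) && !is.na(fit$score))) best <- fit
  }
  best
}

#' Replay speed from the standard decoder's MAP positions
#'
#' Picks the most probable position bin per time bin and differentiates
#' (central differences, Gaussian-smoothed absolute value).
#'
#' @param post posterior matrix from [standard_posterior()].
#' @param smooth_sd Gaussian smoothing SD in seconds (default 2.5 ms).
#' @return speed series in cm/s (one value per time bin).
#' @export
map_speed <- function(post, smooth_sd = 0.0025) {
  centers <- attr(post, "centers"); dt <- attr(post, "dt")
  mp <- map_position(post, centers)
  estimate_speed(mp$position, dt = dt, smooth_sd = smooth_sd)
}

#' Shuffle control: resample encoding positions with replacement
#'
#' Breaks the relationship between spiking and position by resampling the
#' position samples (with replacement) while preserving spike times,
#' waveform marks, and the movement mask.
#'
#' @param linpos a `linearized_position` data.frame.
#' @param seed integer seed.
#' @return a shuffled `linearized_position`.
#' @export
shuffle_positions_resample <- function(linpos, seed = 1L) {
  set.seed(as.integer(seed))
  idx <- sample.int(nrow(linpos), nrow(linpos), replace = TRUE)
  out <- linpos
  cols <- c("segment_id", "linear_position", "x_proj", "y_proj")
  out[cols] <- linpos[idx, cols]
  out
}

#' Shuffle control: permute well-to-well runs and circularly shift positions
#'
#' Permutes the order of the run segments and applies an independent
#' circular shift to the positions within each run, preserving local
#' correlation structure while destroying the global spike-position
#' relationship. Samples outside every run keep their original positions.
#'
#' @param linpos a `linearized_position` data.frame.
#' @param run_intervals data.frame with `start_s`, `end_s` delimiting the
#'   well-to-well runs.
#' @param seed integer seed.
#' @return a shuffled `linearized_position`.
#' @export
shuffle_runs_circular <- function(linpos, run_intervals, seed = 1L) {
  set.seed(as.integer(seed))
  idx_runs <- lapply(seq_len(nrow(run_intervals)), function(r)
    which(linpos$time_s >= run_intervals$start_s[r] &
            linpos$time_s < run_intervals$end_s[r]))
  idx_runs <- idx_runs[lengths(idx_runs) > 0L]
  if (!length(idx_runs)) return(linpos)
  cols <- c("segment_id", "linear_position", "x_proj", "y_proj")
  shifted <- lapply(idx_runs, function(ii) {
    n <- length(ii)
    off <- sample.int(n, 1L) - 1L
    ii[((seq_len(n) - 1L + off) %% n) + 1L]
  })
  perm <- sample.int(length(idx_runs))
  source_idx <- unlist(shifted[perm], use.names = FALSE)
  target_idx <- unlist(idx_runs, use.names = FALSE)
  n <- min(length(source_idx), length(target_idx))
  out <- linpos
  out[target_idx[seq_len(n)], cols] <- linpos[source_idx[seq_len(n)], cols]
  out
}
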
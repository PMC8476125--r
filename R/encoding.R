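# Encoding models fit during movement: per-cell spline GLM place fields
# (sorted spikes) and per-tetrode kernel joint mark intensities (clusterless).

#' Arm layout intervals of a track graph
#' @return data.frame arm, start, end (1D layout cm)
#' @noRd
arm_intervals <- function(track) {
  e <- track$edges
  do.call(rbind, lapply(split(seq_len(nrow(e)), e$arm), function(idx)
    data.frame(arm = e$arm[idx[1L]], start = min(e$start_1d[idx]),
               end = max(e$start_1d[idx] + e$length[idx]))))
}

#' Cubic B-spline basis over the track layout, knots every `knot_spacing` cm
#'
#' Bases are built per arm independently so they never bridge the 1D layout
#' gaps between arms; positions outside an arm get zero weight from that
#' arm's bases. The basis excludes the intercept (zero-constrained relative
#' to the baseline rate).
#' @noRd
spline_basis <- function(track, x, knot_spacing = 5) {
  arms <- arm_intervals(track)
  blocks <- lapply(seq_len(nrow(arms)), function(a) {
    a0 <- arms$start[a]; a1 <- arms$end[a]
    inner <- if (a1 - a0 > 2 * knot_spacing)
      seq(a0 + knot_spacing, a1 - knot_spacing, by = knot_spacing) else numeric(0)
    inside <- x >= a0 - 1e-9 & x <= a1 + 1e-9
    B <- matrix(0, length(x), length(inner) + 3L)
    if (any(inside)) {
      xi <- pmin(pmax(x[inside], a0), a1)
      B[inside, ] <- splines::bs(xi, knots = inner, degree = 3L,
                                 Boundary.knots = c(a0, a1))
    }
    B
  })
  do.call(cbind, blocks)
}

#' Penalized Poisson Newton-Raphson for one cell
#'
#' Maximizes sum(N * (X b + log exposure) - exp(X b) * exposure) minus the
#' L2 penalty on the non-intercept coefficients, with step-halving; starts
#' at b = (log(mean rate), 0, ...). `exposure` is the observation time per
#' row in seconds (a scalar is recycled), so rows sharing a design row may
#' be aggregated exactly by summing counts and exposures.
#' @return list(beta, converged, grad_norm, n_iter)
#' @noRd
fit_poisson_cell <- function(X, counts, exposure, l2, tol = 1e-6,
                             max_iter = 100L) {
  p <- ncol(X)
  if (length(exposure) == 1L) exposure <- rep(exposure, length(counts))
  pen <- c(0, rep(l2, p - 1L))
  mean_rate <- max(sum(counts) / sum(exposure), 1e-10)
  beta <- c(log(mean_rate), rep(0, p - 1L))
  log_expo <- log(exposure)
  pll <- function(b) {
    eta <- drop(X %*% b)
    sum(counts * (eta + log_expo) - exp(eta) * exposure) - sum(pen * b^2)
  }
  ll_old <- pll(beta)
  grad_norm <- Inf
  for (it in seq_len(max_iter)) {
    mu <- exp(drop(X %*% beta)) * exposure
    grad <- drop(crossprod(X, counts - mu)) - 2 * pen * beta
    grad_norm <- max(abs(grad))
    if (grad_norm < tol) return(list(beta = beta, converged = TRUE,
                                     grad_norm = grad_norm, n_iter = it - 1L))
    H <- crossprod(X, X * mu) + diag(2 * pen, p)
    step <- tryCatch(solve(H, grad), error = function(e)
      solve(H + diag(1e-8, p), grad))
    # step-halving on penalized likelihood decrease
    s <- 1
    repeat {
      beta_new <- beta + s * step
      ll_new <- pll(beta_new)
      if (is.finite(ll_new) && ll_new >= ll_old - 1e-12) break
      s <- s / 2
      if (s < 1e-8) { beta_new <- beta; ll_new <- ll_old; break }
    }
    beta <- beta_new; ll_old <- ll_new
  }
  mu <- exp(drop(X %*% beta)) * exposure
  grad <- drop(crossprod(X, counts - mu)) - 2 * pen * beta
  list(beta = beta, converged = max(abs(grad)) < tol,
       grad_norm = max(abs(grad)), n_iter = max_iter)
}

#' Fit the sorted-spikes encoding model (spline GLM place fields)
#'
#' For each cell, fits a Poisson GLM with log link on cubic B-spline bases
#' over linear position (knots every `knot_spacing` cm per arm, intercept
#' plus zero-constrained spline terms) by Newton-Raphson maximization of the
#' L2-penalized log-likelihood, using only encoding-period samples (running
#' speed greater than `speed_threshold`). The fitted rate map is evaluated on
#' the grid bin centers.
#'
#' @param spikes a [spike_train_set()].
#' @param linpos a `linearized_position` data.frame (needs `time_s`,
#'   `linear_position`, `speed`).
#' @param grid a 1D [make_grid_1d()] grid.
#' @param knot_spacing spline knot spacing in cm (default 5).
#' @param l2 L2 penalty on spline coefficients (default 0.5).
#' @param speed_threshold movement speed threshold in cm/s (default 4).
#' @param tol Newton-Raphson gradient infinity-norm tolerance.
#' @param max_iter Newton-Raphson iteration cap.
#' @return object of class `sorted_encoder` with fields `beta` (p x n_cells),
#'   `rate_maps` (n_bins x n_cells, Hz), `converged`, `grad_norm`,
#'   `mean_rates`, plus the fitting parameters and grid.
#' @export
fit_sorted_encoder <- function(spikes, linpos, grid, knot_spacing = 5,
                               l2 = 0.5, speed_threshold = 4, tol = 1e-6,
                               max_iter = 100L) {
  stopifnot(inherits(spikes, "spike_train_set"),
            inherits(grid, "position_grid"))
  if (grid$kind != "1d") stop_param("sorted encoder needs a 1D grid")
  dt <- stats::median(diff(linpos$time_s))
  edges <- c(linpos$time_s - dt / 2, linpos$time_s[nrow(linpos)] + dt / 2)
  counts <- bin_spike_counts(spikes, edges)
  move <- which(!is.na(linpos$speed) & linpos$speed > speed_threshold &
                  linpos$valid)
  if (!length(move)) stop_param("no encoding-period (movement) samples")
  # the design depends on position alone, so samples at identical positions
  # aggregate exactly: sum their counts and exposure times
  move_pos <- linpos$linear_position[move]
  upos <- unique(move_pos)
  gidx <- match(move_pos, upos)
  exposure <- tabulate(gidx, nbins = length(upos)) * dt
  agg_counts <- rowsum(counts[move, , drop = FALSE], gidx)
  X <- cbind(1, spline_basis(attr(linpos, "track") %||% grid$track,
                             upos, knot_spacing))
  Xg <- cbind(1, spline_basis(grid$track, grid$bin_centers, knot_spacing))
  n_cells <- ncol(counts)
  beta <- matrix(0, ncol(X), n_cells)
  rate_maps <- matrix(0, length(grid$bin_centers), n_cells)
  converged <- logical(n_cells); gnorm <- numeric(n_cells)
  for (i in seq_len(n_cells)) {
    ni <- agg_counts[, i]
    if (sum(ni) == 0L) {
      warning(sprintf("cell %d has no movement-period spikes; rate map pinned near zero", i))
      beta[1L, i] <- log(1e-5)
      rate_maps[, i] <- 1e-5
      converged[i] <- TRUE
      next
    }
    fit <- fit_poisson_cell(X, ni, exposure, l2, tol, max_iter)
    if (!fit$converged)
      warning(sprintf("cell %d: Newton-Raphson not converged (grad norm %.3g)",
                      i, fit$grad_norm))
    beta[, i] <- fit$beta
    gnorm[i] <- fit$grad_norm
    converged[i] <- fit$converged
    rate_maps[, i] <- exp(drop(Xg %*% fit$beta))
  }
  structure(list(beta = beta, rate_maps = rate_maps, grid = grid,
                 knot_spacing = knot_spacing, l2 = l2,
                 speed_threshold = speed_threshold, dt = dt,
                 converged = converged, grad_norm = gnorm,
                 cell_ids = spikes$cell_ids,
                 mean_rates = colSums(counts[move, , drop = FALSE]) /
                   (length(move) * dt)),
            class = "sorted_encoder")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.sorted_encoder <- function(x, ...) {
  cat(sprintf("Sorted-spikes encoder: %d cells, %d grid bins, knots every %g cm, L2 = %g\n",
              ncol(x$rate_maps), nrow(x$rate_maps), x$knot_spacing, x$l2))
  cat(sprintf("  peak rates %.1f-%.1f Hz; %d/%d cells converged\n",
              min(apply(x$rate_maps, 2, max)), max(x$rate_maps),
              sum(x$converged), length(x$converged)))
  invisible(x)
}

#' @export
coef.sorted_encoder <- function(object, ...) object$beta

#' Predict place-field rates at new positions
#'
#' @param object a `sorted_encoder`.
#' @param newdata linear positions in cm (default: the grid bin centers).
#' @param ... unused.
#' @return matrix `length(newdata)` x n_cells of rates in Hz.
#' @export
predict.sorted_encoder <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$rate_maps)
  Xn <- cbind(1, spline_basis(object$grid$track, newdata, object$knot_spacing))
  exp(Xn %*% object$beta)
}

#' @export
plot.sorted_encoder <- function(x, ...) {
  matplot(x$grid$bin_centers, x$rate_maps, type = "l", lty = 1,
          xlab = "linear position (cm)", ylab = "rate (Hz)",
          main = "fitted place fields", ...)
  invisible(x)
}

#' @export
summary.sorted_encoder <- function(object, ...) {
  pk <- apply(object$rate_maps, 2L, which.max)
  data.frame(cell_id = object$cell_ids,
             peak_rate_hz = apply(object$rate_maps, 2L, max),
             peak_position_cm = object$grid$bin_centers[pk],
             mean_rate_hz = object$mean_rates,
             converged = object$converged)
}

# ---- clusterless ----------------------------------------------------------

#' Fit the clusterless encoding model (kernel joint mark intensity)
#'
#' Estimates, per tetrode, the Gaussian product-kernel densities over
#' position and the four waveform-amplitude mark dimensions: the occupancy
#' \eqn{\pi(x)}, the spike occupancy \eqn{p_i(x)}, and the joint density
#' \eqn{p_i(x, m)}, all trained on movement-period samples, plus the mean
#' firing rate \eqn{\mu_i}. The ground rate is
#' \eqn{\Lambda_i(x) = \mu_i p_i(x)/\pi(x)} and the joint mark intensity is
#' \eqn{\lambda_i(x, m) = \mu_i p_i(x, m)/\pi(x)}. Densities are floored at
#' 1e-15 before division so rates stay finite in never-visited bins.
#'
#' @param marks a [marked_spike_set()].
#' @param linpos a `linearized_position` data.frame.
#' @param grid a 1D [make_grid_1d()] grid.
#' @param bw_pos position kernel SD in cm (default 6.0).
#' @param bw_mark mark kernel SD in microvolts (default 24.0).
#' @param speed_threshold movement speed threshold in cm/s (default 4).
#' @return object of class `clusterless_encoder`.
#' @export
fit_clusterless_encoder <- function(marks, linpos, grid, bw_pos = 6.0,
                                    bw_mark = 24.0, speed_threshold = 4) {
  stopifnot(inherits(marks, "marked_spike_set"),
            inherits(grid, "position_grid"))
  if (grid$kind != "1d") stop_param("clusterless encoder needs a 1D grid")
  check_positive(bw_pos, "bw_pos"); check_positive(bw_mark, "bw_mark")
  dt <- stats::median(diff(linpos$time_s))
  move <- !is.na(linpos$speed) & linpos$speed > speed_threshold & linpos$valid
  if (!any(move)) stop_param("no encoding-period (movement) samples")
  move_pos <- linpos$linear_position[move]
  move_dur <- sum(move) * dt
  centers <- grid$bin_centers
  # occupancy density pi(x) on the grid
  pi_x <- rowMeans(outer(centers, move_pos,
                         function(g, p) dnorm(g - p, sd = bw_pos)))
  tets <- list()
  keep <- logical(length(marks$tetrodes))
  for (i in seq_along(marks$tetrodes)) {
    tt <- marks$tetrodes[[i]]
    if (!length(tt$times)) { warning(sprintf(
      "tetrode %s empty; excluded", marks$tetrode_ids[i])); next }
    # nearest position sample per spike; keep movement-period spikes
    si <- findInterval(tt$times, c(linpos$time_s - dt / 2, Inf),
                       rightmost.closed = FALSE)
    si <- pmin(pmax(si, 1L), nrow(linpos))
    ok <- move[si]
    if (!any(ok)) { warning(sprintf(
      "tetrode %s has no movement-period spikes; excluded",
      marks$tetrode_ids[i])); next }
    sp <- linpos$linear_position[si[ok]]
    sm <- tt$marks[ok, , drop = FALSE]
    kpos <- outer(centers, sp, function(g, p) dnorm(g - p, sd = bw_pos))
    tets[[length(tets) + 1L]] <- list(
      id = marks$tetrode_ids[i],
      train_pos = sp, train_marks = sm,
      kpos = kpos,                       # n_bins x n_train
      p_x = rowMeans(kpos),
      mu = sum(ok) / move_dur)
    keep[i] <- TRUE
  }
  if (!length(tets)) stop_param("no usable tetrode")
  floor_d <- 1e-15
  lambda_ground <- vapply(tets, function(tt)
    tt$mu * pmax(tt$p_x, floor_d) / pmax(pi_x, floor_d),
    numeric(length(centers)))
  structure(list(tetrodes = tets, pi_x = pi_x,
                 lambda_ground = lambda_ground,  # n_bins x n_tetrodes, Hz
                 bw_pos = bw_pos, bw_mark = bw_mark, floor = floor_d,
                 grid = grid, dt = dt, speed_threshold = speed_threshold),
            class = "clusterless_encoder")
}

#' @export
print.clusterless_encoder <- function(x, ...) {
  cat(sprintf("Clusterless encoder: %d tetrodes, %d grid bins, bw %g cm / %g uV\n",
              length(x$tetrodes), length(x$pi_x), x$bw_pos, x$bw_mark))
  cat(sprintf("  mean rates: %s Hz\n",
              paste(sprintf("%.1f", vapply(x$tetrodes, `[[`, numeric(1), "mu")),
                    collapse = ", ")))
  invisible(x)
}

#' Evaluate the joint position-mark density p_i(x, m) on the grid
#'
#' @param encoder a `clusterless_encoder`.
#' @param tetrode tetrode index within the encoder.
#' @param marks matrix n_spikes x 4 of query marks (uV).
#' @return matrix n_bins x n_spikes of joint densities.
#' @export
joint_mark_density <- function(encoder, tetrode, marks) {
  stopifnot(inherits(encoder, "clusterless_encoder"))
  marks <- as.matrix(marks)
  if (ncol(marks) != 4L)
    stop_param("mark dimensionality mismatch: expected 4 channels")
  tt <- encoder$tetrodes[[tetrode]]
  n_train <- length(tt$train_pos)
  # mark kernel weights: n_train x n_spikes product over 4 channels
  w <- matrix(1, n_train, nrow(marks))
  for (d in 1:4)
    w <- w * outer(tt$train_marks[, d], marks[, d],
                   function(a, b) dnorm(a - b, sd = encoder$bw_mark))
  (tt$kpos %*% w) / n_train
}
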
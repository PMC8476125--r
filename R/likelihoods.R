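# Per-time-bin observation log-likelihoods over the position grid. All
# computation is in log space up to an additive per-bin constant; the filter
# subtracts the per-slice maximum before exponentiating.

#' Uniform time-bin edges for an event
#'
#' @param duration event duration in seconds.
#' @param dt bin width in seconds (default 2 ms).
#' @return numeric vector of bin edges (length n_bins + 1).
#' @export
event_time_edges <- function(duration, dt = 0.002) {
  check_positive(duration, "duration")
  check_positive(dt, "dt")
  n <- max(1L, round(duration / dt))
  seq(0, by = dt, length.out = n + 1L)
}

#' Construct a likelihood matrix object
#' @noRd
likelihood_matrix <- function(loglik, time_edges) {
  if (any(!is.finite(loglik)))
    stop_param("log-likelihood must be finite everywhere")
  structure(list(loglik = loglik, time_edges = time_edges,
                 dt = diff(time_edges)[1L]),
            class = "likelihood_matrix")
}

#' @export
print.likelihood_matrix <- function(x, ...) {
  cat(sprintf("Likelihood matrix: %d time bins x %d position bins (dt = %g ms)\n",
              nrow(x$loglik), ncol(x$loglik), 1000 * x$dt))
  invisible(x)
}

#' Poisson log-likelihood of sorted spikes over the position grid
#'
#' For each time bin k and grid bin x,
#' \eqn{\log p(O_k|x) = \sum_i N_{k,i} \log(\lambda_i(x)\Delta) -
#' \lambda_i(x)\Delta} (up to the factorial constant). Bins with no spikes
#' still contribute the \eqn{-\lambda\Delta} term, so silence carries
#' information about low-rate positions.
#'
#' @param model a [fit_sorted_encoder()] model.
#' @param spikes a [spike_train_set()] restricted to the event.
#' @param time_edges uniform bin edges in seconds (see [event_time_edges()]).
#' @return a `likelihood_matrix`.
#' @export
sorted_likelihood <- function(model, spikes, time_edges) {
  stopifnot(inherits(model, "sorted_encoder"),
            inherits(spikes, "spike_train_set"))
  dts <- diff(time_edges)
  if (max(abs(dts - dts[1L])) > 1e-9) stop_param("time bins must be uniform")
  dt <- dts[1L]
  counts <- bin_spike_counts(spikes, time_edges)
  if (ncol(counts) != ncol(model$rate_maps))
    stop_param("cell count mismatch between spikes and encoder")
  rates <- pmax(model$rate_maps, 1e-10)        # n_bins x n_cells
  loglik <- counts %*% t(log(rates * dt)) -
    matrix(colSums(t(rates)) * dt, nrow(counts), nrow(rates), byrow = TRUE)
  likelihood_matrix(loglik, time_edges)
}

#' Clusterless log-likelihood of marked spikes over the position grid
#'
#' For each time bin k and grid bin x,
#' \eqn{\log p(O_k|x) = \sum_i [\sum_j \log(\lambda_i(x, m_{k,j})\Delta) -
#' \Lambda_i(x)\Delta]} where \eqn{\lambda_i(x,m) = \mu_i p_i(x,m)/\pi(x)} is
#' the joint mark intensity and \eqn{\Lambda_i(x)} the tetrode ground rate.
#' Multiple spikes from one tetrode within a bin all enter the product.
#'
#' @param model a [fit_clusterless_encoder()] model.
#' @param marks a [marked_spike_set()] restricted to the event.
#' @param time_edges uniform bin edges in seconds.
#' @return a `likelihood_matrix`.
#' @export
clusterless_likelihood <- function(model, marks, time_edges) {
  stopifnot(inherits(model, "clusterless_encoder"),
            inherits(marks, "marked_spike_set"))
  dts <- diff(time_edges)
  if (max(abs(dts - dts[1L])) > 1e-9) stop_param("time bins must be uniform")
  dt <- dts[1L]
  n_time <- length(time_edges) - 1L
  n_bins <- length(model$pi_x)
  # silence term: -sum_i Lambda_i(x) dt, identical across time bins
  loglik <- matrix(rep(-rowSums(model$lambda_ground) * dt, each = n_time),
                   n_time, n_bins)
  log_pi <- log(pmax(model$pi_x, model$floor))
  ids <- vapply(model$tetrodes, `[[`, FUN.VALUE = model$tetrodes[[1]]$id, "id")
  for (i in seq_along(marks$tetrodes)) {
    tt <- marks$tetrodes[[i]]
    if (!length(tt$times)) next
    enc_i <- match(marks$tetrode_ids[i], ids)
    if (is.na(enc_i))
      stop_param(sprintf("tetrode %s not present in the encoder",
                         marks$tetrode_ids[i]))
    if (ncol(tt$marks) != 4L)
      stop_param("mark dimensionality mismatch: expected 4 channels")
    inside <- tt$times >= time_edges[1L] & tt$times <= time_edges[n_time + 1L]
    if (any(!inside))
      warning(sprintf("%d marked spikes outside the time range were dropped",
                      sum(!inside)))
    if (!any(inside)) next
    bin <- findInterval(tt$times[inside], time_edges, rightmost.closed = TRUE)
    joint <- joint_mark_density(model, enc_i,
                                tt$marks[inside, , drop = FALSE])
    mu <- model$tetrodes[[enc_i]]$mu
    logint <- log(pmax(joint, model$floor)) + log(mu * dt) - log_pi
    for (s in seq_along(bin))
      loglik[bin[s], ] <- loglik[bin[s], ] + logint[, s]
  }
  likelihood_matrix(loglik, time_edges)
}
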
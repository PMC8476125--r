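# The switching state-space model: initial conditions, discrete dynamics
# chain, per-dynamic movement kernels, and the causal filter / acausal
# smoother over the joint (dynamic x position-bin) space.

DYNAMICS_LABELS <- c("stationary", "continuous", "fragmented")

#' Build the switching dynamics model on a position grid
#'
#' The discrete dynamics chain has `stay_prob` on the diagonal and the
#' remaining probability split evenly among the other dynamics; at the 2 ms
#' step the default 0.98 corresponds to a geometric expected dwell time of
#' 100 ms. Movement kernels per ordered dynamic pair: identity (delta) when
#' staying stationary or entering stationary from continuous; a Gaussian
#' random walk (variance `rw_variance`, evaluated on pairwise graph distances
#' then row-normalized so track ends do not leak mass) when staying
#' continuous or entering continuous from stationary; uniform for every pair
#' involving fragmented. The initial condition is uniform over dynamics and
#' position.
#'
#' @param grid a [make_grid_1d()] or [make_grid_2d()] grid.
#' @param stay_prob probability of staying in the same dynamic per time step,
#'   in (0, 1] (default 0.98).
#' @param rw_variance random-walk variance in cm^2 (default 6.0; SD 2.449 cm,
#'   so 95% of per-step displacements fall within 4.90 cm).
#' @param dynamics character subset of
#'   `c("stationary", "continuous", "fragmented")` (all three by default).
#' @return object of class `dynamics_model` with the discrete matrix, the
#'   per-pair movement kernels, the joint transition matrix over
#'   (dynamic, bin) states, and the initial distribution.
#' @export
build_dynamics_model <- function(grid, stay_prob = 0.98, rw_variance = 6.0,
                                 dynamics = DYNAMICS_LABELS) {
  stopifnot(inherits(grid, "position_grid"))
  if (!is.numeric(stay_prob) || stay_prob <= 0 || stay_prob > 1)
    stop_param("`stay_prob` must lie in (0, 1]")
  check_positive(rw_variance, "rw_variance")
  dynamics <- match.arg(dynamics, DYNAMICS_LABELS, several.ok = TRUE)
  nd <- length(dynamics)
  nb <- length(grid$widths)
  w <- grid$widths
  discrete <- matrix(if (nd > 1L) (1 - stay_prob) / (nd - 1L) else 0, nd, nd,
                     dimnames = list(dynamics, dynamics))
  diag(discrete) <- if (nd > 1L) stay_prob else 1
  identity_k <- diag(nb)
  uniform_k <- matrix(rep(w / sum(w), each = nb), nb, nb)
  rw <- dnorm(grid$graph_distance, mean = 0, sd = sqrt(rw_variance)) *
    matrix(w, nb, nb, byrow = TRUE)
  rw <- rw / rowSums(rw)
  kernel_for <- function(from, to) {
    if (from == "fragmented" || to == "fragmented") uniform_k
    else if (to == "stationary") identity_k
    else rw                                  # to == "continuous"
  }
  kernels <- lapply(dynamics, function(a)
    lapply(setNames(dynamics, dynamics), function(b) kernel_for(a, b)))
  names(kernels) <- dynamics
  joint <- matrix(0, nd * nb, nd * nb)
  for (a in seq_len(nd)) for (b in seq_len(nd))
    joint[(a - 1L) * nb + seq_len(nb), (b - 1L) * nb + seq_len(nb)] <-
      discrete[a, b] * kernels[[a]][[b]]
  init <- rep(w / sum(w) / nd, nd)
  structure(list(labels = dynamics, discrete = discrete, kernels = kernels,
                 joint = joint, init = init, stay_prob = stay_prob,
                 rw_variance = rw_variance, n_bins = nb, grid = grid,
                 grid_hash = content_hash(grid$bin_centers)),
            class = "dynamics_model")
}

#' @export
print.dynamics_model <- function(x, ...) {
  cat(sprintf("Dynamics model: {%s} on %d bins; stay prob %g (expected dwell %g ms at 2 ms steps); RW variance %g cm^2\n",
              paste(x$labels, collapse = ", "), x$n_bins, x$stay_prob,
              2 / (1 - x$stay_prob), x$rw_variance))
  invisible(x)
}

#' Wrap filter/smoother output as a posterior object
#' @noRd
new_replay_posterior <- function(causal, acausal, predicted, lik, dyn, grid,
                                 log_evidence) {
  n_time <- nrow(causal); nd <- length(dyn$labels); nb <- dyn$n_bins
  shape <- function(m) {
    a <- array(m, dim = c(n_time, nb, nd))
    aperm(a, c(1L, 3L, 2L))                  # time x dynamic x bin
  }
  structure(list(causal = shape(causal),
                 acausal = if (is.null(acausal)) NULL else shape(acausal),
                 predicted = predicted,      # kept flat for the smoother
                 causal_flat = causal,
                 time = (lik$time_edges[-1L] + head(lik$time_edges, -1L)) / 2,
                 dt = lik$dt, labels = dyn$labels, grid = grid, dyn = dyn,
                 log_evidence = log_evidence),
            class = "replay_posterior")
}

#' Run the causal (forward) filter
#'
#' Recursively computes \eqn{p(x_k, I_k | O_{1:k})} from the initial
#' condition, approximating position integrals by Riemann sums over the grid
#' bins; every slice is renormalized (the per-slice log normalizer
#' accumulates into the log evidence).
#'
#' @param lik a `likelihood_matrix` (from [sorted_likelihood()] or
#'   [clusterless_likelihood()]).
#' @param dyn a [build_dynamics_model()].
#' @param grid the grid the likelihood and dynamics were built on (kept for
#'   downstream summaries).
#' @return a `replay_posterior` with the causal estimate (acausal slot empty
#'   until [acausal_smoother()] is run).
#' @export
causal_filter <- function(lik, dyn, grid = dyn$grid) {
  stopifnot(inherits(lik, "likelihood_matrix"),
            inherits(dyn, "dynamics_model"))
  if (ncol(lik$loglik) != dyn$n_bins)
    stop_param("likelihood and dynamics model use different grids")
  out <- ssm_forward(lik$loglik, dyn$joint, dyn$init)
  new_replay_posterior(out$causal, NULL, out$predicted, lik, dyn, grid,
                       out$log_evidence)
}

#' Run the acausal (backward) smoother
#'
#' Starting from the final causal slice, recursively computes
#' \eqn{p(x_k, I_k | O_{1:T})} by the two-filter ratio form: the causal
#' estimate times the transition-weighted ratio of the smoothed to the
#' one-step predictive distribution at k+1 (terms with zero predictive mass
#' contribute zero). At k = T the acausal equals the causal estimate.
#'
#' @param post a `replay_posterior` from [causal_filter()].
#' @return the posterior with the `acausal` slot filled.
#' @export
acausal_smoother <- function(post) {
  stopifnot(inherits(post, "replay_posterior"))
  ac <- ssm_backward(post$causal_flat, post$predicted, post$dyn$joint)
  n_time <- nrow(ac); nb <- post$dyn$n_bins; nd <- length(post$labels)
  a <- aperm(array(ac, dim = c(n_time, nb, nd)), c(1L, 3L, 2L))
  post$acausal <- a
  post
}

#' Decode an event with the switching state-space model
#'
#' Orchestrates likelihood evaluation (sorted or clusterless, chosen by the
#' encoder class), the causal filter, and the acausal smoother, in uniform
#' time bins (2 ms by default).
#'
#' @param data a [spike_train_set()] (with a `sorted_encoder`) or a
#'   [marked_spike_set()] (with a `clusterless_encoder`) covering the event.
#' @param encoder the fitted encoding model.
#' @param dyn a [build_dynamics_model()]; defaults to the standard
#'   three-dynamics model on the encoder's grid.
#' @param dt time bin width in seconds (default 2 ms).
#' @param time_edges optional explicit bin edges (overrides `dt`).
#' @return a `replay_posterior` with causal and acausal estimates and
#'   provenance metadata in `$provenance`.
#' @export
decode_replay <- function(data, encoder,
                          dyn = build_dynamics_model(encoder$grid),
                          dt = 0.002, time_edges = NULL) {
  if (is.null(time_edges)) time_edges <- event_time_edges(data$duration, dt)
  lik <- if (inherits(encoder, "sorted_encoder")) {
    stopifnot(inherits(data, "spike_train_set"))
    sorted_likelihood(encoder, data, time_edges)
  } else if (inherits(encoder, "clusterless_encoder")) {
    stopifnot(inherits(data, "marked_spike_set"))
    clusterless_likelihood(encoder, data, time_edges)
  } else stop_param("`encoder` must be a sorted or clusterless encoder")
  post <- causal_filter(lik, dyn, grid = encoder$grid)
  post <- acausal_smoother(post)
  post$provenance <- list(
    encoder_class = class(encoder)[1L], dt = lik$dt,
    stay_prob = dyn$stay_prob, rw_variance = dyn$rw_variance,
    n_bins = dyn$n_bins, grid_hash = dyn$grid_hash,
    data_hash = content_hash(data))
  post
}

#' @export
print.replay_posterior <- function(x, ...) {
  cat(sprintf("Replay posterior: %d x %g ms bins, %d dynamics x %d position bins (%s)\n",
              length(x$time), 1000 * x$dt, length(x$labels),
              dim(x$causal)[3L],
              if (is.null(x$acausal)) "causal only" else "causal + acausal"))
  invisible(x)
}

#' @export
summary.replay_posterior <- function(object, threshold = 0.80, ...) {
  if (is.null(object$acausal)) object <- acausal_smoother(object)
  marg <- dynamics_marginal(object)
  cls <- classify_dynamics(marg, threshold = threshold, time = object$time,
                           dt = object$dt)
  list(dynamics_probability = colMeans(marg),
       classification = table(cls$label),
       segments = attr(cls, "segments"),
       log_evidence = object$log_evidence)
}

#' @export
plot.replay_posterior <- function(x, which = c("position", "dynamics"), ...) {
  which <- match.arg(which)
  if (is.null(x$acausal)) x <- acausal_smoother(x)
  if (which == "position") {
    pm <- position_marginal(x)
    image(x$time, x$grid$bin_centers, pm, xlab = "time (s)",
          ylab = "linear position (cm)", main = "posterior of position", ...)
  } else {
    dm <- dynamics_marginal(x)
    matplot(x$time, dm, type = "l", lty = 1, ylim = c(0, 1),
            xlab = "time (s)", ylab = "probability",
            main = "probability of each dynamic", ...)
    legend("topright", legend = x$labels, col = seq_along(x$labels), lty = 1,
           bty = "n")
  }
  invisible(x)
}
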
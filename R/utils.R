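# Internal helpers shared across modules.

#' Stop with a parameter error message
#' @noRd
stop_param <- function(...) stop(..., call. = FALSE)

#' Check a single positive finite number
#' @noRd
check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop_param(sprintf("`%s` must be a single positive finite number", name))
  invisible(x)
}

#' Gaussian smoothing of a regularly sampled series
#'
#' Convolves with a Gaussian kernel truncated at 4 standard deviations;
#' edges are handled by renormalizing the partial kernel so the smoother is
#' mass-preserving for constant inputs.
#'
#' @param x numeric series.
#' @param sd kernel standard deviation in samples. `sd = 0` returns `x`.
#' @return smoothed numeric series, same length as `x`.
#' @keywords internal
#' @noRd
gaussian_smooth <- function(x, sd) {
  if (sd <= 0) return(x)
  half <- max(1L, ceiling(4 * sd))
  k <- dnorm(seq(-half, half), sd = sd)
  n <- length(x)
  num <- stats::filter(c(rep(0, half), x, rep(0, half)), k, sides = 2)
  den <- stats::filter(c(rep(0, half), rep(1, n), rep(0, half)), k, sides = 2)
  as.numeric(num[(half + 1):(half + n)] / den[(half + 1):(half + n)])
}

#' numpy-style gradient: central differences inside, one-sided at the ends
#' @noRd
gradient1d <- function(x, dt) {
  n <- length(x)
  if (n < 2L) return(rep(0, n))
  g <- numeric(n)
  g[1L] <- (x[2L] - x[1L]) / dt
  g[n] <- (x[n] - x[n - 1L]) / dt
  if (n > 2L) g[2:(n - 1L)] <- (x[3:n] - x[1:(n - 2L)]) / (2 * dt)
  g
}

#' Contiguous runs of equal values
#' @return data.frame with columns value, start, end (1-based inclusive idx)
#' @noRd
rle_runs <- function(v) {
  r <- rle(as.character(v))
  end <- cumsum(r$lengths)
  data.frame(value = r$values, start = end - r$lengths + 1L, end = end,
             stringsAsFactors = FALSE)
}

#' Stable content hash used for provenance manifests
#'
#' FNV-1a over the serialized object; no cryptographic intent, just a
#' reproducible fingerprint for configs and arrays.
#' @noRd
content_hash <- function(x) {
  bytes <- serialize(x, NULL, version = 2L)
  # drop serialization header (R version stamps) so hashes are stable
  bytes <- bytes[-seq_len(14L)]
  h <- 2166136261
  for (b in as.integer(bytes)) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}
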
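# Standard-decoder baselines: 20 ms posterior, Radon and regression line
# fits, MAP speed, and the encoding shuffles.

test_that("the 20 ms posterior aggregates ten 2 ms likelihoods exactly", {
  enc <- fixture_sorted_encoder()
  seqs <- fixture_sequence()
  post20 <- standard_posterior(enc, seqs, dt = 0.020)
  ll2 <- sorted_likelihood(enc, seqs, event_time_edges(0.280, 0.002))$loglik
  # direct recomputation: sum the 2 ms log-likelihoods within each 20 ms bin
  agg <- rowsum(ll2, rep(seq_len(14), each = 10))
  agg_post <- exp(agg - apply(agg, 1, max))
  agg_post <- agg_post / rowSums(agg_post)
  expect_equal(unclass(post20), agg_post, tolerance = 1e-10,
               ignore_attr = TRUE)
  # flat rates: flat posterior (uniform prior ~ likelihood)
  flat_enc <- structure(list(rate_maps = matrix(4, 60, 2),
                             grid = fixture_grid()),
                        class = "sorted_encoder")
  sp <- spike_train_set(list(0.01, 0.03), duration = 0.04)
  flat <- standard_posterior(flat_enc, sp, dt = 0.020)
  expect_lt(diff(range(flat)), 1e-12)
})

test_that("the Radon fit recovers a perfect line with maximal significance", {
  centers <- fixture_grid()$bin_centers
  n_t <- 10
  true_slope <- 600                       # cm/s
  post <- matrix(1e-12, n_t, 60)
  tt <- (seq_len(n_t) - 0.5) * 0.020
  pos0 <- 90 + true_slope * (tt - mean(tt))   # stays inside the track
  for (k in seq_len(n_t))
    post[k, which.min(abs(centers - pos0[k]))] <- 1
  post <- post / rowSums(post)
  attr(post, "time") <- tt; attr(post, "dt") <- 0.020
  attr(post, "centers") <- centers
  fit <- radon_fit(post, n_shuffles = 200, seed = 1)
  slope_step <- 2e4 / 100
  expect_lt(abs(fit$slope - true_slope), slope_step + 1e-9)
  expect_lte(fit$p_value, 1 / 201)
  expect_equal(fit$score, 1, tolerance = 0.01)
})

test_that("the Radon best line matches an exhaustive scan", {
  set.seed(13)
  centers <- seq(1.5, 58.5, by = 3)       # 20 bins
  post <- matrix(rexp(6 * 20), 6, 20); post <- post / rowSums(post)
  tt <- (1:6 - 0.5) * 0.020
  attr(post, "time") <- tt; attr(post, "dt") <- 0.020
  attr(post, "centers") <- centers
  fit <- radon_fit(post, n_shuffles = 0, seed = 1, n_slopes = 41)
  # independent double-loop oracle over the same line family
  slopes <- seq(-1e4, 1e4, length.out = 41)
  best <- -Inf
  t_rel <- tt - mean(tt)
  for (sl in slopes) for (ic in centers) {
    pos <- ic + sl * t_rel
    bin <- round((pos - 1.5) / 3) + 1
    ok <- bin >= 1 & bin <= 20
    sc <- sum(post[cbind(which(ok), bin[ok])]) / 6
    if (sc > best) best <- sc
  }
  expect_equal(fit$score, best, tolerance = 1e-12)
})

test_that("linear regression recovers sloped lines but never stationary ones", {
  centers <- fixture_grid()$bin_centers
  n_t <- 12
  tt <- (seq_len(n_t) - 0.5) * 0.020
  post <- matrix(1e-12, n_t, 60)
  pos0 <- 20 + 500 * (tt - tt[1])
  for (k in seq_len(n_t))
    post[k, which.min(abs(centers - pos0[k]))] <- 1
  post <- post / rowSums(post)
  attr(post, "time") <- tt; attr(post, "dt") <- 0.020
  attr(post, "centers") <- centers
  fit <- linreg_fit(post, n_samples = 500, seed = 2)
  # oracle: closed-form OLS on the noiseless line (slope 500), allowing for
  # the 3 cm discretization
  expect_lt(abs(fit$slope - 500), 30)
  expect_lt(fit$p_value, 1e-6)
  # doubling the samples leaves the estimate unchanged within MC error
  fit2 <- linreg_fit(post, n_samples = 1000, seed = 3)
  expect_lt(abs(fit2$slope - fit$slope), 30)
  # a stationary posterior has zero slope and no significance
  stat_post <- matrix(1e-12, n_t, 60); stat_post[, 20] <- 1
  stat_post <- stat_post / rowSums(stat_post)
  attr(stat_post, "time") <- tt; attr(stat_post, "dt") <- 0.020
  attr(stat_post, "centers") <- centers
  sfit <- linreg_fit(stat_post, n_samples = 500, seed = 4)
  expect_equal(sfit$slope, 0)
  expect_true(is.na(sfit$p_value))        # degenerate samples are flagged
})

test_that("a long stationary posterior can reach Radon significance", {
  # the Radon line family includes zero slope, so sustained stationary
  # structure is detectable (unlike linear regression)
  centers <- fixture_grid()$bin_centers
  n_t <- 10
  tt <- (seq_len(n_t) - 0.5) * 0.020
  post <- matrix(1e-12, n_t, 60); post[, 20] <- 1
  post <- post / rowSums(post)
  attr(post, "time") <- tt; attr(post, "dt") <- 0.020
  attr(post, "centers") <- centers
  fit <- radon_fit(post, n_shuffles = 200, seed = 5)
  expect_equal(fit$slope, 0)                  # zero slope is in the family
  expect_lte(fit$p_value, 0.05)
})

test_that("MAP speed of a line posterior equals its slope", {
  centers <- seq(1.5, 178.5, by = 3)
  n_t <- 10
  tt <- (seq_len(n_t) - 0.5) * 0.020
  post <- matrix(1e-12, n_t, 60)
  for (k in seq_len(n_t)) post[k, 10 + 2 * (k - 1)] <- 1   # 6 cm / 20 ms
  post <- post / rowSums(post)
  attr(post, "time") <- tt; attr(post, "dt") <- 0.020
  attr(post, "centers") <- centers
  expect_equal(map_speed(post), rep(300, n_t), tolerance = 1e-9)
})

test_that("radon p-values are super-uniform under the circular-shift null", {
  set.seed(21)
  centers <- seq(1.5, 58.5, by = 3)
  n_null <- 40
  pvals <- vapply(seq_len(n_null), function(e) {
    post <- matrix(rexp(8 * 20), 8, 20); post <- post / rowSums(post)
    # null posterior: independently cycle each time bin
    for (k in 1:8) {
      off <- sample.int(20, 1) - 1
      if (off > 0) post[k, ] <- post[k, c((off + 1):20, 1:off)]
    }
    tt <- (1:8 - 0.5) * 0.020
    attr(post, "time") <- tt; attr(post, "dt") <- 0.020
    attr(post, "centers") <- centers
    radon_fit(post, n_shuffles = 99, seed = e, n_slopes = 21)$p_value
  }, numeric(1))
  for (a in c(0.1, 0.25, 0.5))
    expect_lte(mean(pvals <= a), a + 3 * sqrt(a * (1 - a) / n_null))
})

test_that("encoding shuffles preserve spikes and position marginals", {
  fe <- fixture_encoding()
  lp <- fe$linpos
  sh <- shuffle_positions_resample(lp, seed = 5)
  expect_identical(sh$time_s, lp$time_s)
  expect_identical(sh$speed, lp$speed)
  # resampling preserves the occupancy distribution (moments match closely)
  expect_lt(abs(mean(sh$linear_position) - mean(lp$linear_position)), 3)
  expect_lt(suppressWarnings(
    ks.test(sh$linear_position, lp$linear_position)$statistic), 0.02)
  # circular run shuffle: one run reduces to a circular shift
  runs1 <- data.frame(start_s = 0, end_s = max(lp$time_s) + 1)
  sh1 <- shuffle_runs_circular(lp, runs1, seed = 6)
  n <- nrow(lp)
  shift_found <- FALSE
  for (off in 0:(n - 1)) {
    idx <- ((seq_len(n) - 1 + off) %% n) + 1
    if (isTRUE(all.equal(sh1$linear_position, lp$linear_position[idx]))) {
      shift_found <- TRUE; break
    }
  }
  expect_true(shift_found)
  # multiple runs: the multiset of run position blocks is preserved
  runs <- data.frame(start_s = c(0, 60, 120), end_s = c(60, 120, 181))
  sh3 <- shuffle_runs_circular(lp, runs, seed = 7)
  expect_equal(sort(sh3$linear_position), sort(lp$linear_position),
               tolerance = 1e-12)
  # shuffling destroys spike-position mutual information (plug-in estimate)
  spikes10 <- fe$run$spikes$spike_times[[10]]
  dt <- 0.002
  bin_of <- function(pos) findInterval(pos, seq(0, 180, by = 18),
                                       rightmost.closed = TRUE)
  mi <- function(lpx) {
    idx <- pmin(pmax(round(spikes10 / dt + 0.5), 1), nrow(lpx))
    pb <- bin_of(lpx$linear_position[idx])
    occ <- table(factor(bin_of(lpx$linear_position), levels = 1:10)) /
      nrow(lpx)
    ps <- table(factor(pb, levels = 1:10)) / length(pb)
    sum(ps * log(pmax(ps, 1e-12) / pmax(occ, 1e-12)))
  }
  expect_gt(mi(lp), mi(shuffle_positions_resample(lp, seed = 8)) + 0.2)
})
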
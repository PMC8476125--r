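# Synthetic-data generators: Poisson encoding runs, the three-segment test
# sequence, constant-speed sweeps, marks, and ripple-bearing LFP.

test_that("Poisson encoding run reproduces the place-field rates", {
  bank <- fixture_bank()
  expect_equal(bank$peak_locations, seq(0, 180, by = 10))
  # empirical rate map converges to lambda_i(x): 200 traversals, +/- 10%
  enc <- simulate_encoding_run(bank, n_traversals = 200, seed = 7)
  pos <- enc$position$linear_position
  dt <- 0.002
  mid_cells <- 5:15                     # away from the track ends
  for (i in mid_cells) {
    near_peak <- abs(pos - bank$peak_locations[i]) < 1.5
    emp_rate <- sum(enc$spikes$spike_times[[i]] %in%
                      enc$position$time_s[near_peak]) /
      (sum(near_peak) * dt)
    expect_lt(abs(emp_rate - bank$peak_rate) / bank$peak_rate, 0.10)
  }
})

test_that("zero peak rate yields zero spikes; bad parameters are rejected", {
  bank0 <- place_field_bank(peak_rate = 0)
  enc <- simulate_encoding_run(bank0, n_traversals = 2, seed = 1)
  expect_identical(sum(lengths(enc$spikes$spike_times)), 0L)
  expect_error(simulate_encoding_run(fixture_bank(), dt = -0.002),
               "positive")
  expect_error(simulate_encoding_run(fixture_bank(), speed = 0), "positive")
  expect_error(place_field_bank(field_sd = 0), "positive")
})

test_that("spike counts match the analytic Poisson mean over seeds", {
  # one wide-field cell so the rate along the run is analytically known;
  # oracle = sum of lambda(x_t) * dt over the deterministic trajectory
  bank <- place_field_bank(n_cells = 1L, track_length = 60, spacing = 10,
                           field_sd = 6, peak_rate = 15)
  dt <- 0.002; speed <- 30
  n_bin <- ceiling(60 / speed / dt)
  t_mid <- (seq_len(n_bin) - 0.5) * dt
  pos <- pmin(t_mid * speed, 60)        # single traversal, no reflection
  expected <- sum(15 * exp(-(pos - 0)^2 / 72) * dt)
  counts <- vapply(1:200, function(s)
    length(simulate_encoding_run(bank, n_traversals = 1, dt = dt,
                                 speed = speed,
                                 seed = s)$spikes$spike_times[[1]]),
    numeric(1))
  se <- sqrt(expected / 200)            # Poisson SE of the mean
  expect_lt(abs(mean(counts) - expected), 4 * se)
})

test_that("test sequence has the requested segment structure", {
  bank <- fixture_bank()
  seqs <- fixture_sequence()
  expect_equal(seqs$duration, 0.280)
  counts <- bin_spike_counts(seqs, event_time_edges(seqs$duration))
  expect_equal(nrow(counts), 140L)
  expect_true(all(rowSums(counts) == 1L))  # one spike per 2 ms bin
  # stationary opening: a single active cell for 60 ms
  active <- apply(counts, 1L, which.max)
  expect_equal(length(unique(active[1:30])), 1L)
  # continuous middle: activation order equals place-field peak order
  mid <- active[31:125]
  expect_true(all(diff(mid) >= 0))
  # oracle: first-activation order equals the argsort of peak locations
  first_seen <- unique(mid)
  expect_equal(first_seen,
               first_seen[order(bank$peak_locations[first_seen])])
  # reproducible bit-for-bit under a fixed seed
  expect_identical(make_test_sequence(bank, seed = 1),
                   make_test_sequence(bank, seed = 1))
  # single stationary segment: exactly one active cell throughout
  s1 <- make_test_sequence(bank, segments = data.frame(
    kind = "stationary", duration_ms = 60), seed = 1)
  expect_equal(sum(lengths(s1$spike_times) > 0), 1L)
  expect_error(make_test_sequence(bank, segments = data.frame(
    kind = "wiggly", duration_ms = 60)), "unknown segment kind")
  expect_error(make_test_sequence(bank, segments = data.frame(
    kind = "stationary", duration_ms = 3)), "multiples")
})

test_that("constant-speed sweeps are exact deterministic crossing times", {
  bank <- fixture_bank()
  sw <- make_constant_speed_sweep(bank, c(1, 100, 10000))
  # oracle: crossing time = peak_location / speed
  for (v in c(1, 100, 10000)) {
    st <- unlist(sw[[as.character(v)]]$spike_times)
    expect_equal(sort(st), pmin(bank$peak_locations / v,
                                sw[[as.character(v)]]$duration - 1e-9),
                 tolerance = 1e-12)
  }
  # adjacent-cell inter-spike interval = spacing / speed (10 s at 1 cm/s);
  # the final crossing is clamped just inside the event window
  st1 <- sort(unlist(sw[["1"]]$spike_times))
  expect_equal(unique(round(diff(st1[1:18]), 9)), 10)
  expect_error(make_constant_speed_sweep(bank, c(10, -1)), "positive")
})

test_that("synthetic marks are Gaussian around well-separated cluster means", {
  bank <- place_field_bank(n_cells = 2L, track_length = 60, spacing = 50)
  means <- default_mark_means(2L)
  expect_true(min(dist(default_mark_means(19L))) >= 3 * 24)
  spikes <- spike_train_set(list(seq(0.001, 0.999, by = 0.002),
                                 seq(0.002, 1, by = 0.002)), duration = 1)
  # degenerate noise: marks equal cluster means
  m0 <- attach_marks(spikes, means, mark_sd = 1e-9, seed = 1)
  got <- m0$tetrodes[[1]]$marks[1, ]
  expect_true(any(vapply(1:2, function(i)
    isTRUE(all.equal(got, means[i, ], tolerance = 1e-6)), logical(1))))
  # single cell: marginal mark density is the cell's Gaussian (KS test)
  one <- spike_train_set(list(runif(1e4)), duration = 1)
  mk <- attach_marks(one, means[1, , drop = FALSE], mark_sd = 10, seed = 2)
  ks <- stats::ks.test(mk$tetrodes[[1]]$marks[, 1], "pnorm",
                       mean = means[1, 1], sd = 10)
  expect_gt(ks$p.value, 0.01)
  expect_error(attach_marks(spikes, means[1, , drop = FALSE]), "n_cells x 4")
  expect_error(attach_marks(spikes, means, mark_sd = 0), "positive")
})

test_that("clusterless decode of a two-cell raster matches the sorted decode", {
  # two cells with mark means 60 uV apart, mark SD 10 uV
  bank <- place_field_bank(n_cells = 2L, track_length = 63, spacing = 60,
                           field_sd = 6, peak_rate = 15)
  enc <- simulate_encoding_run(bank, n_traversals = 30, seed = 5)
  track <- linear_track(63); grid <- make_grid_1d(track)
  lp <- linearized_from_1d(track, enc$position$time_s,
                           enc$position$linear_position,
                           speed = rep(15, nrow(enc$position)))
  means <- rbind(c(120, 120, 120, 120), c(180, 120, 120, 120))
  senc <- fit_sorted_encoder(enc$spikes, lp, grid)
  cenc <- fit_clusterless_encoder(attach_marks(enc$spikes, means,
                                               mark_sd = 10, seed = 6),
                                  lp, grid)
  ev <- make_test_sequence(bank, segments = data.frame(
    kind = c("stationary", "fragmented"), duration_ms = c(40, 40)),
    seed = 2, stationary_cell = 1L)
  sp <- decode_replay(ev, senc)
  cp <- decode_replay(attach_marks(ev, means, mark_sd = 10, seed = 7), cenc)
  expect_gt(cor(as.vector(position_marginal(sp)),
                as.vector(position_marginal(cp))), 0.9)
})

test_that("simulated LFP validates intervals and carries ripple bursts", {
  expect_error(simulate_lfp_with_ripples(1, list(c(0.1, 0.3), c(0.2, 0.4))),
               "overlap")
  expect_error(simulate_lfp_with_ripples(1, list(c(0.5, 1.5))), "within")
  expect_error(simulate_lfp_with_ripples(1, ripple_freq = 100), "ripple band")
  lfp <- simulate_lfp_with_ripples(2, list(c(0.5, 0.55)), amplitude = 5,
                                   seed = 3)
  inside <- lfp$time_s >= 0.5 & lfp$time_s < 0.55
  expect_gt(sd(lfp$traces[inside, 1]), 2 * sd(lfp$traces[!inside, 1]))
})
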
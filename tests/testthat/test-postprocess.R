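# Posterior summaries: marginals, classification, HPD, MAP, speed, and
# event-level bookkeeping.

test_that("marginals integrate the joint posterior correctly", {
  grid <- fixture_grid()
  dyn <- build_dynamics_model(grid)
  set.seed(3)
  post <- acausal_smoother(causal_filter(
    make_lik(matrix(rnorm(6 * 60), 6, 60)), dyn, grid))
  dm <- dynamics_marginal(post); pm <- position_marginal(post)
  expect_equal(rowSums(dm), rep(1, 6), tolerance = 1e-10)
  expect_equal(rowSums(pm), rep(1, 6), tolerance = 1e-10)
  # dense-summation oracle
  k <- 4L
  oracle_dyn <- vapply(1:3, function(d) sum(post$acausal[k, d, ]), numeric(1))
  oracle_pos <- vapply(1:60, function(j) sum(post$acausal[k, , j]), numeric(1))
  expect_equal(unname(dm[k, ]), oracle_dyn, tolerance = 1e-12)
  expect_equal(pm[k, ], oracle_pos, tolerance = 1e-12)
  # degenerate posterior concentrated in one dynamic
  deg <- post
  deg$acausal[, 2:3, ] <- 0
  deg$acausal <- deg$acausal / array(apply(deg$acausal, 1, sum),
                                     dim(deg$acausal))
  expect_equal(unname(dynamics_marginal(deg)[1, ]), c(1, 0, 0))
  expect_equal(position_marginal(deg)[2, ], deg$acausal[2, 1, ])
})

test_that("five-category classification follows the 0.80 rule", {
  m <- rbind(c(1, 0, 0),          # stationary
             c(0.6, 0.4, 0),      # stationary-continuous mixture
             c(0, 0.85, 0.15),    # continuous
             c(0.1, 0.5, 0.4),    # fragmented-continuous mixture
             c(0, 0.1, 0.9),      # fragmented
             c(0.5, 0.3, 0.2))    # sums to exactly 0.8: NOT above threshold
  cls <- classify_dynamics(m)
  expect_equal(as.character(cls$label),
               c("stationary", "stationary-continuous-mixture", "continuous",
                 "fragmented-continuous-mixture", "fragmented",
                 "unclassified"))
  expect_error(classify_dynamics(m, threshold = 0.4), "0.5, 1")
  expect_error(classify_dynamics(m[, 1:2, drop = FALSE]), "three")
  # segments partition the event
  seg <- attr(cls, "segments")
  expect_equal(sum(seg$duration_ms), nrow(m) * 2)
})

test_that("raising the threshold never classifies a new bin", {
  set.seed(8)
  p <- matrix(rexp(300 * 3), 300, 3)
  p <- p / rowSums(p)
  lab80 <- classify_dynamics(p, 0.80)$label
  lab95 <- classify_dynamics(p, 0.95)$label
  newly <- lab80 == "unclassified" & lab95 != "unclassified"
  expect_false(any(newly))
})

test_that("HPD regions match exhaustive threshold search", {
  w <- rep(3, 60)
  # point mass: minimal 3 cm region
  pm <- matrix(0, 1, 60); pm[1, 17] <- 1
  expect_equal(hpd_region(pm, widths = w)$size, 3)
  # uniform: ceil(0.95 * 60) = 57 bins -> 171 cm
  un <- matrix(1 / 60, 1, 60)
  expect_equal(hpd_region(un, widths = w)$size, 57 * 3)
  # bimodal: the region is the union of both bumps; oracle = exhaustive scan
  # over candidate thresholds h
  x <- seq(1.5, 178.5, by = 3)
  dens <- 0.6 * dnorm(x, 40, 6) + 0.4 * dnorm(x, 140, 6)
  dens <- dens / sum(dens)
  got <- hpd_region(matrix(dens, 1), widths = w)
  oracle_size <- min(vapply(sort(dens), function(h) {
    mem <- dens >= h
    if (sum(dens[mem]) >= 0.95 - 1e-12) sum(w[mem]) else Inf
  }, numeric(1)))
  expect_equal(got$size, oracle_size)
  expect_gt(sum(got$members[1, x < 90]), 0)
  expect_gt(sum(got$members[1, x > 90]), 0)
  # size shrinks (weakly) as the posterior concentrates
  sizes <- vapply(c(24, 12, 6, 3), function(s) {
    d <- dnorm(x, 90, s); hpd_region(matrix(d / sum(d), 1), widths = w)$size
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("MAP positions use the dense argmax with low-index ties", {
  x <- fixture_grid()$bin_centers
  pm <- matrix(0, 2, 60)
  pm[1, 25] <- 1
  pm[2, c(10, 40)] <- 0.5                 # tie: lowest bin index wins
  got <- map_position(pm, x)
  expect_equal(got$bin, c(25L, 10L))
  expect_equal(got$position, x[c(25, 10)])
  set.seed(2)
  r <- matrix(runif(5 * 60), 5, 60)
  expect_equal(map_position(r, x)$bin,
               vapply(1:5, function(k) which.max(r[k, ]), integer(1)))
})

test_that("speed estimation: gradient, smoothing, and segment rules", {
  expect_equal(estimate_speed(rep(30, 50)), rep(0, 50))
  ramp <- seq(0, by = 3, length.out = 50)    # one 3 cm bin per 2 ms
  expect_equal(estimate_speed(ramp), rep(1500, 50), tolerance = 1e-9)
  # per-segment means exclude segments shorter than 20 ms
  m <- rbind(matrix(rep(c(1, 0, 0), 20), ncol = 3, byrow = TRUE),
             matrix(rep(c(0, 1, 0), 5), ncol = 3, byrow = TRUE),
             matrix(rep(c(0, 0, 1), 15), ncol = 3, byrow = TRUE))
  cls <- classify_dynamics(m)
  seg <- estimate_speed(ramp[1:40], classification = cls)
  expect_equal(nrow(seg), 3L)
  expect_true(is.na(seg$mean_speed[2]))      # 10 ms segment excluded
  expect_equal(seg$mean_speed[1], 1500, tolerance = 1e-9)
})

test_that("event summaries aggregate categories, flags, and distances", {
  grid <- fixture_grid()
  # constructed track: 40 ms stationary at 50 cm, then 60 ms continuous
  m <- rbind(matrix(rep(c(0.9, 0.1, 0), 20), ncol = 3, byrow = TRUE),
             matrix(rep(c(0.05, 0.9, 0.05), 30), ncol = 3, byrow = TRUE))
  cls <- classify_dynamics(m)
  pm <- matrix(1e-9, 50, 60)
  stat_bin <- which.min(abs(grid$bin_centers - 50))
  for (k in 1:20) pm[k, stat_bin] <- 1
  for (k in 21:50) pm[k, min(stat_bin + (k - 20), 60)] <- 1
  pm <- pm / rowSums(pm)
  # animal sits at 10 cm: the stationary representation is 40 cm away
  summ <- summarize_event(cls, pm, grid, animal_xy = c(10, 0))
  expect_setequal(summ$categories, c("stationary", "continuous"))
  expect_true(summ$spatially_coherent)
  expect_false(summ$spatially_incoherent)
  expect_true(summ$non_local_stationary)
  expect_equal(unname(summ$durations_ms["stationary"]), 40)
  expect_equal(unname(summ$durations_ms["continuous"]), 60)
  expect_equal(sum(summ$durations_ms), summ$event_duration_ms)
  expect_equal(unname(summ$mean_distance_cm["stationary"]), 40,
               tolerance = 3)
  # same event at the animal's position: local, still coherent
  summ2 <- summarize_event(cls, pm, grid,
                           animal_xy = c(grid$bin_centers[stat_bin], 0))
  expect_false(summ2$non_local_stationary)
  # without the animal's position, distances are flagged absent
  summ3 <- summarize_event(cls, pm, grid)
  expect_false(summ3$distance_available)
  expect_true(all(is.na(summ3$mean_distance_cm)))
})
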
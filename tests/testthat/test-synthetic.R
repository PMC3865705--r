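test_that("trajectory has one sample per frame, stays in the arena, and is reproducible", {
  tr <- generate_trajectory(900, seed = 11)
  expect_equal(nrow(tr), 27000)
  expect_true(all(tr$x_cm >= 0 & tr$x_cm <= 40))
  expect_true(all(tr$y_cm >= 0 & tr$y_cm <= 40))
  tr2 <- generate_trajectory(900, seed = 11)
  expect_identical(tr, tr2)
  expect_false(identical(tr, generate_trajectory(900, seed = 12)))
  expect_error(generate_trajectory(0), "duration")
  expect_error(generate_trajectory(10, frame_rate = -1), "frame_rate")
})

test_that("default motion covers all four quadrants and matches the target speed", {
  for (seed in 1:5) {
    tr <- generate_trajectory(900, seed = seed)
    qx <- tr$x_cm > 20; qy <- tr$y_cm > 20
    frac <- c(mean(!qx & !qy), mean(qx & !qy), mean(!qx & qy), mean(qx & qy))
    expect_true(all(frac >= 0.05),
                label = sprintf("quadrant coverage at seed %d", seed))
  }
  mean_sp <- vapply(1:10, function(s)
    mean(trajectory_speed(generate_trajectory(300, seed = s))), 0)
  expect_lt(abs(mean(mean_sp) - 5) / 5, 0.15)
})

test_that("tuning evaluation follows the Gaussian closed form", {
  arena <- arena_spec()
  spec <- tuning_spec(c(20, 20), sigma = 5, peak = 10, baseline = 1)
  expect_equal(evaluate_tuning(spec, 20, 20), 10)
  expect_equal(evaluate_tuning(spec, 25, 20), 1 + 9 * exp(-1 / 2))
  spec0 <- tuning_spec(c(20, 20), sigma = 5, peak = 10, baseline = 0)
  expect_equal(evaluate_tuning(spec0, 30, 20), 10 * exp(-2), tolerance = 1e-12)
  expect_error(evaluate_tuning(spec, 41, 20), "outside")
  expect_error(tuning_spec(c(20, 20), sigma = 5, peak = 1, baseline = 2))
})

test_that("Poisson thinning matches the integrated intensity", {
  # zero intensity -> no spikes
  spec0 <- tuning_spec(c(20, 20), 5, peak = 0, baseline = 0)
  tr <- traj_stationary(100, 10, 10)
  expect_length(simulate_spikes(spec0, tr, seed = 1), 0)
  # constant 5 Hz for 1000 s: count within 5000 +/- 3*sqrt(5000)
  spec <- tuning_spec(c(10, 10), 5, peak = 5, baseline = 5)
  trl <- traj_stationary(1000, 10, 10)
  counts <- vapply(1:10, function(s)
    length(simulate_spikes(spec, trl, seed = s)), 0L)
  expect_true(all(abs(counts - 5000) <= 3 * sqrt(5000)))
})

test_that("empirical peak pixel lands within one bin of the tuning center", {
  tr <- generate_trajectory(900, seed = 21)
  spec <- tuning_spec(c(26, 14), sigma = 4, peak = 12, baseline = 0.2)
  s <- simulate_spikes(spec, tr, seed = 22)
  sm <- rate_map_set(tr, s)$smoothed
  f <- detect_place_field(sm)
  true_bin <- c(bin_index(26), bin_index(14))
  expect_lte(max(abs(f$peak_pixel - true_bin)), 1)
})

test_that("spike times are consistent with time rescaling of the intensity", {
  # constant rate: rescaled intervals are exactly exponential(1)
  spec <- tuning_spec(c(10, 10), 5, peak = 4, baseline = 4)
  tr <- traj_stationary(300, 10, 10)
  s <- simulate_spikes(spec, tr, seed = 31)
  expect_gt(length(s), 500)
  u <- diff(s * 4)
  d <- suppressWarnings(stats::ks.test(u, "pexp", 1)$statistic)
  expect_lt(d, 1.63 / sqrt(length(u)))
  # spatially tuned rate along a real trajectory
  trj <- generate_trajectory(900, seed = 32)
  spec2 <- tuning_spec(c(15, 25), sigma = 6, peak = 10, baseline = 1)
  s2 <- simulate_spikes(spec2, trj, seed = 33)
  expect_gt(length(s2), 500)
  lam <- evaluate_tuning(spec2, trj$x_cm, trj$y_cm)
  Lam <- cumsum(lam) / attr(trj, "frame_rate")
  ls <- stats::approx(trj$time_s, Lam, xout = s2)$y
  u2 <- diff(ls)
  d2 <- suppressWarnings(stats::ks.test(u2, "pexp", 1)$statistic)
  expect_lt(d2, 1.63 / sqrt(length(u2)))
})

test_that("condition effects transform tunings as specified", {
  spec <- tuning_spec(c(10, 30), sigma = 4, peak = 8, baseline = 0.5)
  expect_identical(apply_condition(spec, condition_effect("SAL")), spec)
  full_pull <- condition_effect("CPP", width_multiplier = 2,
                                peak_attenuation = 1, com_pull_to_center = 1)
  out <- apply_condition(spec, full_pull)
  expect_equal(unname(out$center), c(20, 20))
  expect_equal(out$sigma, 8)
  expect_error(condition_effect("CPP", width_multiplier = 0), "width")
  expect_error(condition_effect("SAL", width_multiplier = 2), "identity")
})

test_that("wider tunings yield larger detected fields downstream", {
  tr <- generate_trajectory(900, seed = 41)
  sizes <- vapply(c(3, 6), function(sg) {
    spec <- tuning_spec(c(20, 20), sigma = sg, peak = 10, baseline = 0.2)
    s <- simulate_spikes(spec, tr, seed = 42)
    detect_place_field(rate_map_set(tr, s)$smoothed)$size_cm2
  }, 0)
  expect_gt(sizes[2], sizes[1])
})

test_that("session generator honors class probabilities and determinism", {
  probs <- class_probs()
  ses <- generate_opm_session(n_units = 8, probs = probs, seed = 51)
  ses2 <- generate_opm_session(n_units = 8, probs = probs, seed = 51)
  expect_identical(ses$spikes, ses2$spikes)
  expect_identical(ses$ground_truth, ses2$ground_truth)
  # spikes inside their trial spans
  trials <- ses$manifest$trials
  all_spk <- unlist(ses$spikes)
  in_span <- rep(FALSE, length(all_spk))
  for (k in seq_len(nrow(trials)))
    in_span <- in_span | (all_spk >= trials$start_s[k] &
                            all_spk <= trials$end_s[k])
  expect_true(all(in_span))
  # trajectories unaffected by cohort size
  ses3 <- generate_opm_session(n_units = 3, probs = probs, seed = 51)
  expect_identical(ses$trajectories, ses3$trajectories)
})

test_that("degenerate all-stable cohort has zero ground-truth displacement", {
  probs <- class_probs(
    t1_t2 = c(stable = 1, unstable = 0, emerging = 0, vanishing = 0,
              inactive = 0),
    t2_t3 = c(stable = 1, unstable = 0, emerging = 0, vanishing = 0,
              inactive = 0))
  ses <- generate_opm_session(n_units = 12, probs = probs, seed = 52,
                              spikes = FALSE)
  gt <- ses$ground_truth
  expect_true(all(gt$class_t1_t2 == "stable"))
  expect_true(all(gt$class_t2_t3 == "stable"))
  for (u in unique(gt$unit)) {
    g <- gt[gt$unit == u, ]
    expect_equal(diff(range(g$center_x)), 0)
    expect_equal(diff(range(g$center_y)), 0)
  }
})

test_that("emerging-unit counts fall inside the exact binomial 99% interval", {
  probs <- class_probs(
    t1_t2 = c(stable = 0.5, unstable = 0.1, emerging = 0.2, vanishing = 0.1,
              inactive = 0.1))
  ses <- generate_opm_session(n_units = 200, probs = probs, seed = 53,
                              spikes = FALSE)
  gt <- ses$ground_truth[ses$ground_truth$trial == "T1", ]
  n_emer <- sum(gt$class_t1_t2 == "emerging")
  ci <- stats::qbinom(c(0.005, 0.995), 200, 0.2)
  expect_gte(n_emer, ci[1])
  expect_lte(n_emer, ci[2])
  expect_error(generate_opm_session(
    n_units = 5, probs = class_probs(t1_t2 = c(
      stable = 0.5, unstable = 0.5, emerging = 0.5, vanishing = 0,
      inactive = 0))), "sum to 1")
})
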
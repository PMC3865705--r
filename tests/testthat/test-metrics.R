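test_that("rate summaries are the max and occupancy-weighted mean", {
  const <- make_map(matrix(4, 20, 20))
  rs <- summarize_rates(const)
  expect_equal(rs$peak_hz, 4)
  expect_equal(rs$mean_hz, 4)
  # rates (8,0,0,0) on 4 pixels, uniform occupancy -> peak 8, mean 2
  rate <- matrix(0, 2, 2); rate[1, 1] <- 8
  rs2 <- summarize_rates(make_map(rate, arena = arena_spec(4, 2)))
  expect_equal(rs2$peak_hz, 8)
  expect_equal(rs2$mean_hz, 2)
  # random map against explicit loops
  mp <- random_map(3)
  rs3 <- summarize_rates(mp)
  expect_equal(rs3$peak_hz, max(mp$rate[mp$mask]))
  expect_equal(rs3$mean_hz,
               sum(mp$rate[mp$mask] * mp$dwell[mp$mask]) /
                 sum(mp$dwell[mp$mask]))
  expect_lte(rs3$mean_hz, rs3$peak_hz)
})

test_that("spatial information reproduces hand-computed values", {
  # uniform firing carries no information
  expect_equal(spatial_information(make_map(matrix(3, 20, 20)))$bits_per_spike, 0)
  # single firing pixel among 4, uniform occupancy: log2(4) bits/spike
  rate <- matrix(0, 2, 2); rate[1, 1] <- 8
  si <- spatial_information(make_map(rate, arena = arena_spec(4, 2)))
  expect_equal(si$bits_per_second, 4)
  expect_equal(si$bits_per_spike, 2)
  # three pixels, occupancy (0.5, 0.25, 0.25), rates (1, 2, 4):
  # F = 2, bits/s = 0.5*1*log2(1/2) + 0.25*2*log2(1) + 0.25*4*log2(2) = 0.5
  rate3 <- matrix(0, 2, 2); dwell3 <- matrix(0, 2, 2)
  rate3[1, 1] <- 1; rate3[2, 1] <- 2; rate3[1, 2] <- 4
  dwell3[1, 1] <- 2; dwell3[2, 1] <- 1; dwell3[1, 2] <- 1
  mask3 <- dwell3 > 0
  si3 <- spatial_information(make_map(rate3, dwell3, mask3,
                                      arena = arena_spec(4, 2)))
  expect_equal(si3$bits_per_second, 0.5)
  expect_equal(si3$bits_per_spike, 0.25)
  expect_error(
    spatial_information(make_map(matrix(0, 20, 20))), "silent unit")
})

test_that("SI is nonnegative and matches the direct-summation oracle", {
  for (seed in 1:25) {
    mp <- random_map(seed)
    si <- spatial_information(mp)
    or <- oracle_si(mp)
    expect_equal(si$bits_per_second, or$bits_per_second, tolerance = 1e-12)
    expect_equal(si$bits_per_spike, or$bits_per_spike, tolerance = 1e-12)
    expect_gte(si$bits_per_second, 0)
  }
})

test_that("SI decreases with tuning width on simulated fields", {
  tr <- generate_trajectory(900, seed = 61)
  si <- vapply(c(3, 5, 8, 12), function(sg) {
    spec <- tuning_spec(c(20, 20), sigma = sg, peak = 12, baseline = 0.3)
    s <- simulate_spikes(spec, tr, seed = 62)
    spatial_information(rate_map_set(tr, s)$smoothed)$bits_per_spike
  }, 0)
  expect_true(all(diff(si) < 0))
})

test_that("place-field detection implements the contiguity rules", {
  # 3x3 block of 10 Hz on zero background: 9 pixels, 36 cm^2
  rate <- matrix(0, 20, 20); rate[9:11, 9:11] <- 10
  f <- detect_place_field(make_map(rate))
  expect_equal(f$n_pixels, 9)
  expect_equal(f$size_cm2, 36)
  expect_true(all(f$pixels[, "ix"] %in% 9:11))
  # 6 suprathreshold pixels fail the 8-pixel minimum
  rate6 <- matrix(0, 20, 20); rate6[9:11, 9:10] <- 10
  expect_null(detect_place_field(make_map(rate6)))
  # secondary blob without the peak is discarded
  rate2 <- matrix(0, 20, 20)
  rate2[3:5, 3:5] <- 10; rate2[14:16, 14:16] <- 8
  f2 <- detect_place_field(make_map(rate2))
  expect_equal(f2$n_pixels, 9)
  expect_true(all(f2$pixels[, "ix"] %in% 3:5))
  # all-zero map: no field (not an error)
  expect_null(detect_place_field(make_map(matrix(0, 20, 20))))
  # diagonal-only contact does not join components (edge sharing only)
  rated <- matrix(0, 20, 20)
  rated[5:7, 5:7] <- 10   # peak blob, 9 px
  rated[8, 8] <- 10       # touches only at a corner
  fd <- detect_place_field(make_map(rated))
  expect_equal(fd$n_pixels, 9)
})

test_that("field size is invariant to positive scaling", {
  mp <- smooth_rate_map(random_map(9))
  f1 <- detect_place_field(mp)
  expect_false(is.null(f1))
  mp5 <- mp; mp5$rate <- mp$rate * 5
  f5 <- detect_place_field(mp5)
  expect_equal(f1$size_cm2, f5$size_cm2)
  expect_equal(f1$pixels, f5$pixels)
})

test_that("field detection agrees with exhaustive component search", {
  for (seed in 1:60) {
    # smoothed random maps give realistic multi-blob structures
    mp <- smooth_rate_map(random_map(seed))
    f <- detect_place_field(mp)
    or <- oracle_field(mp)
    if (is.null(or)) expect_null(f)
    else {
      n <- nrow(mp$rate)
      got <- sort((f$pixels[, "iy"] - 1L) * n + f$pixels[, "ix"])
      expect_equal(got, or)
    }
  }
})

test_that("center of mass is the rate-weighted pixel-center mean", {
  # single active pixel
  rate <- matrix(0, 20, 20); rate[3, 8] <- 5
  expect_equal(unname(center_of_mass(make_map(rate), "full"))[1:2], c(5, 15))
  # two pixels at x = 1 (rate 1) and x = 3 (rate 3): COM x = 2.5
  arena <- arena_spec(4, 2)
  rate2 <- matrix(0, 2, 2); rate2[1, 1] <- 1; rate2[2, 1] <- 3
  com2 <- center_of_mass(make_map(rate2, arena = arena), "full")
  expect_equal(com2[["x"]], 2.5)
  expect_equal(com2[["y"]], 1)
  # radially symmetric field about (10, 10)
  ctr <- pixel_centers(1:20, 1:20)
  g <- outer(1:20, 1:20, function(i, j)
    exp(-(((i - 0.5) * 2 - 10)^2 + ((j - 0.5) * 2 - 10)^2) / 50))
  com3 <- center_of_mass(make_map(g), "full")
  expect_lt(max(abs(com3[1:2] - c(10, 10))), 1)
  # oracle equivalence on random maps
  for (seed in 1:20) {
    mp <- random_map(seed)
    expect_equal(unname(center_of_mass(mp, "full"))[1:2],
                 unname(oracle_com_full(mp))[1:2], tolerance = 1e-12)
  }
  expect_error(center_of_mass(make_map(matrix(0, 20, 20)), "full"),
               "zero total rate")
})

test_that("COM shift is the distance between per-trial COMs", {
  rate <- matrix(0, 20, 20); rate[5:7, 5:7] <- 10
  a <- make_map(rate)
  expect_equal(com_shift(a, a)$distance_cm, 0)
  # field translated by (3, 4) cm -> 5-cm shift (3-4-5 triangle)
  rateb <- matrix(0, 20, 20)
  rateb[5:7 + 3 / 2, 5:7 + 2] <- 10
  b <- make_map(rateb)
  # translate by whole pixels: dx = 2 px * 2cm... use (4, 6) px offset of 1.5?
  cs <- com_shift(a, b)
  expect_equal(cs$distance_cm, sqrt(sum(cs$vector^2)))
})

test_that("a 3-4-5 field translation gives a 5-cm shift", {
  # 2-cm bins: shift by 1.5 bins is not representable, so use a 1-cm grid
  arena <- arena_spec(40, 1)
  rate <- matrix(0, 40, 40); rate[10:12, 10:12] <- 10
  a <- make_map(rate, arena = arena)
  rateb <- matrix(0, 40, 40); rateb[13:15, 14:16] <- 10
  b <- make_map(rateb, arena = arena)
  cs <- com_shift(a, b)
  expect_equal(cs$distance_cm, 5)
  expect_equal(unname(cs$vector), c(3, 4))
})

test_that("similarity score is an affine-invariant Pearson correlation", {
  mp <- smooth_rate_map(random_map(11))
  expect_equal(similarity_score(mp, mp), 1)
  aff <- mp; aff$rate <- 2 * mp$rate + 1
  expect_equal(similarity_score(mp, aff), 1)
  neg <- mp; neg$rate <- -mp$rate
  expect_equal(similarity_score(mp, neg), -1)
  const <- make_map(matrix(2, 20, 20))
  s <- similarity_score(mp, const)
  expect_true(is.na(s))
  expect_match(attr(s, "reason"), "constant")
})

test_that("object proximity picks the nearest object and reports ties", {
  lay <- object_layout(sites = c("NW", "NE"))
  p <- object_proximity(c(x = 10, y = 10), lay, "T2")
  expect_equal(p$distance_cm, 20)
  expect_equal(p$label, "left")
  at_obj <- object_proximity(c(x = 10, y = 30), lay, "T2")
  expect_equal(at_obj$distance_cm, 0)
  tie <- object_proximity(c(x = 20, y = 20), lay, "T2")
  expect_equal(tie$distance_cm, sqrt(200))
  expect_setequal(tie$label, c("left", "right"))
})

test_that("unit screening applies the width and refractory criteria", {
  expect_equal(as.character(screen_unit(250, TRUE)), "putative_pyramidal")
  expect_equal(as.character(screen_unit(200, TRUE)), "putative_interneuron")
  r1 <- screen_unit(300, FALSE)
  expect_equal(as.character(r1), "rejected")
  r2 <- screen_unit(NA, TRUE)
  expect_equal(as.character(r2), "rejected")
  expect_match(attr(r2, "reason"), "no waveform")
})
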
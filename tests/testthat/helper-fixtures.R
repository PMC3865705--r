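# Fixture builders and independent brute-force oracles.
# Oracles are deliberately written as plain double loops, independent of the
# package's vectorized/flood-fill implementations.

# Build a rate_map object directly from matrices (for unit fixtures).
make_map <- function(rate, dwell = NULL, mask = NULL, arena = arena_spec(),
                     smoothed = FALSE, min_occupancy = 0.1) {
  n <- nrow(rate)
  if (is.null(mask)) mask <- matrix(TRUE, n, n)
  if (is.null(dwell)) dwell <- matrix(1, n, n)
  r <- rate
  r[!mask] <- NA_real_
  overall <- sum(r[mask] * dwell[mask]) / sum(dwell[mask])
  structure(list(rate = r, mask = mask, dwell = dwell,
                 overall_rate = overall, smoothed = smoothed,
                 arena = arena, min_occupancy = min_occupancy),
            class = "rate_map")
}

# A stationary (single-pixel) trajectory.
traj_stationary <- function(duration, x, y, frame_rate = 30,
                            arena = arena_spec(), t0 = 0) {
  n <- round(duration * frame_rate)
  out <- data.frame(time_s = t0 + (seq_len(n) - 1) / frame_rate,
                    x_cm = rep(x, n), y_cm = rep(y, n))
  attr(out, "frame_rate") <- frame_rate
  attr(out, "arena") <- arena
  class(out) <- c("trajectory", "data.frame")
  out
}

# A trajectory from explicit coordinates.
traj_from_xy <- function(x, y, frame_rate = 30, arena = arena_spec(),
                         t0 = 0) {
  out <- data.frame(time_s = t0 + (seq_along(x) - 1) / frame_rate,
                    x_cm = x, y_cm = y)
  attr(out, "frame_rate") <- frame_rate
  attr(out, "arena") <- arena
  class(out) <- c("trajectory", "data.frame")
  out
}

# Random valid rate map on the default grid.
random_map <- function(seed, p_valid = 0.85, smoothed = FALSE) {
  set.seed(seed)
  n <- 20
  rate <- matrix(stats::rexp(n * n, 1 / 2), n, n)
  mask <- matrix(stats::runif(n * n) < p_valid, n, n)
  if (!any(mask)) mask[1, 1] <- TRUE
  dwell <- matrix(stats::runif(n * n, 0.1, 3), n, n)
  make_map(rate, dwell, mask, smoothed = smoothed)
}

# Oracle: renormalized masked convolution by explicit double loop.
oracle_smooth <- function(map, kernel) {
  n <- nrow(map$rate); m <- ncol(map$rate)
  r <- (nrow(kernel) - 1) / 2
  out <- matrix(NA_real_, n, m)
  for (i in 1:n) for (j in 1:m) {
    if (!map$mask[i, j]) next
    num <- 0; den <- 0
    for (a in -r:r) for (b in -r:r) {
      ii <- i + a; jj <- j + b
      if (ii < 1 || ii > n || jj < 1 || jj > m) next
      if (!map$mask[ii, jj]) next
      w <- kernel[a + r + 1, b + r + 1]
      num <- num + w * map$rate[ii, jj]
      den <- den + w
    }
    out[i, j] <- num / den
  }
  out
}

# Oracle: Skaggs information by explicit summation.
oracle_si <- function(map) {
  f <- c(); p <- c()
  for (i in seq_len(nrow(map$rate))) for (j in seq_len(ncol(map$rate))) {
    if (map$mask[i, j]) {
      f <- c(f, map$rate[i, j]); p <- c(p, map$dwell[i, j])
    }
  }
  p <- p / sum(p)
  FF <- sum(p * f)
  bps <- 0
  for (k in seq_along(f))
    if (f[k] > 0) bps <- bps + p[k] * f[k] * log2(f[k] / FF)
  list(bits_per_second = bps, bits_per_spike = bps / FF)
}

# Oracle: exhaustive 4-connected component search by iterated label merging
# (independent of the package's flood fill).
oracle_components <- function(mask) {
  n <- nrow(mask); m <- ncol(mask)
  lab <- matrix(0L, n, m)
  lab[mask] <- seq_len(sum(mask))
  repeat {
    changed <- FALSE
    for (i in 1:n) for (j in 1:m) {
      if (!mask[i, j]) next
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        ii <- i + d[1]; jj <- j + d[2]
        if (ii < 1 || ii > n || jj < 1 || jj > m) next
        if (mask[ii, jj] && lab[ii, jj] < lab[i, j]) {
          lab[i, j] <- lab[ii, jj]; changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  lab
}

oracle_field <- function(map, threshold_frac = 0.1, min_pixels = 8) {
  peak <- max(map$rate[map$mask])
  if (peak <= 0) return(NULL)
  supra <- map$mask & !is.na(map$rate) & map$rate >= threshold_frac * peak
  lab <- oracle_components(supra)
  peak_idx <- which(map$mask & map$rate == peak)[1]
  if (!supra[peak_idx]) return(NULL)
  px <- which(lab == lab[peak_idx])
  if (length(px) < min_pixels) return(NULL)
  sort(px)
}

# Oracle: rate-weighted COM by explicit loop over all valid pixels.
oracle_com_full <- function(map) {
  sx <- sy <- sw <- 0
  bs <- map$arena$bin_size
  for (i in seq_len(nrow(map$rate))) for (j in seq_len(ncol(map$rate))) {
    if (!map$mask[i, j]) next
    w <- map$rate[i, j]
    sx <- sx + w * (i - 0.5) * bs
    sy <- sy + w * (j - 0.5) * bs
    sw <- sw + w
  }
  c(x = sx / sw, y = sy / sw)
}
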
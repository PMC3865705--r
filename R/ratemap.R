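#' Bin a trajectory into an occupancy map
#'
#' Each video frame contributes one frame period of dwell time to the pixel
#' containing the tracked position, so the map total equals the trajectory
#' duration to within one frame period.
#'
#' @param traj A `trajectory` (columns `time_s`, `x_cm`, `y_cm`).
#' @param arena An [arena_spec()] defining the grid.
#' @return Object of class `occupancy_map`: `dwell` (n x n matrix, seconds;
#'   rows index x bins west to east, columns y bins south to north),
#'   `total_s`, `frame_period`, `arena`.
#' @export
bin_occupancy <- function(traj, arena = arena_spec()) {
  bad <- which(!is_inside_arena(traj$x_cm, traj$y_cm, arena))
  if (length(bad))
    stop(sprintf("position outside the arena at frame %d", bad[1]))
  fr <- attr(traj, "frame_rate")
  if (is.null(fr)) fr <- 1 / stats::median(diff(traj$time_s))
  ix <- bin_index(traj$x_cm, arena)
  iy <- bin_index(traj$y_cm, arena)
  n <- arena$n_bins
  dwell <- matrix(0, n, n)
  tab <- table(factor(ix, levels = 1:n), factor(iy, levels = 1:n))
  dwell[] <- as.numeric(tab) / fr
  structure(list(dwell = dwell, total_s = nrow(traj) / fr,
                 frame_period = 1 / fr, arena = arena),
            class = "occupancy_map")
}

#' Bin spikes into a per-pixel count map
#'
#' Each spike is assigned to the pixel of the temporally nearest position
#' sample; a spike exactly equidistant between two frames goes with the
#' earlier frame.
#'
#' @param spikes Numeric vector of spike times, s.
#' @param traj A `trajectory`; all spikes must fall within its time span.
#' @param arena An [arena_spec()].
#' @return Object of class `spike_count_map`: `counts` (n x n matrix),
#'   `n_spikes`, `arena`.
#' @export
bin_spikes <- function(spikes, traj, arena = arena_spec()) {
  tt <- traj$time_s
  if (length(spikes)) {
    out <- spikes < tt[1] | spikes > tt[length(tt)]
    if (any(out))
      stop(sprintf("spike at %.4f s outside the trajectory span",
                   spikes[which(out)[1]]))
  }
  n <- arena$n_bins
  counts <- matrix(0L, n, n)
  if (length(spikes)) {
    lo <- findInterval(spikes, tt)
    lo[lo < 1] <- 1L
    hi <- pmin(lo + 1L, length(tt))
    # nearest frame; tie -> earlier
    idx <- ifelse(spikes - tt[lo] <= tt[hi] - spikes, lo, hi)
    ix <- bin_index(traj$x_cm[idx], arena)
    iy <- bin_index(traj$y_cm[idx], arena)
    tab <- table(factor(ix, levels = 1:n), factor(iy, levels = 1:n))
    counts[] <- as.integer(tab)
  }
  structure(list(counts = counts, n_spikes = length(spikes), arena = arena),
            class = "spike_count_map")
}

#' Compute a firing-rate map with occupancy exclusion
#'
#' Per-pixel rate is spike count divided by dwell time; pixels occupied for
#' less than `min_occupancy` seconds are excluded (invalid, `NA` rate) no
#' matter how many spikes they hold. The overall rate `F` is the
#' occupancy-weighted mean rate over the valid pixels, which equals
#' (spikes on valid pixels) / (dwell on valid pixels).
#'
#' @param occ An `occupancy_map`.
#' @param counts A `spike_count_map` on the same grid.
#' @param min_occupancy Minimum pixel dwell, s (default 0.1).
#' @return Object of class `rate_map`: `rate` (matrix, Hz, `NA` where
#'   invalid), `mask` (logical validity matrix), `dwell`, `overall_rate`,
#'   `smoothed` flag, `arena`, `min_occupancy`.
#' @export
compute_rate_map <- function(occ, counts, min_occupancy = 0.1) {
  stopifnot(inherits(occ, "occupancy_map"), inherits(counts, "spike_count_map"))
  if (occ$arena$n_bins != counts$arena$n_bins ||
      occ$arena$bin_size != counts$arena$bin_size)
    stop("grid mismatch between occupancy and spike-count maps")
  mask <- occ$dwell >= min_occupancy
  if (!any(mask)) stop("no valid pixels: all occupancy below threshold")
  rate <- matrix(NA_real_, nrow(mask), ncol(mask))
  rate[mask] <- counts$counts[mask] / occ$dwell[mask]
  overall <- sum(counts$counts[mask]) / sum(occ$dwell[mask])
  structure(list(rate = rate, mask = mask, dwell = occ$dwell,
                 overall_rate = overall, smoothed = FALSE,
                 arena = occ$arena, min_occupancy = min_occupancy),
            class = "rate_map")
}

#' @export
print.rate_map <- function(x, ...) {
  cat(sprintf("<rate_map>%s %d x %d, %d valid pixels, F = %.3f Hz\n",
              if (x$smoothed) " (smoothed)" else "",
              nrow(x$rate), ncol(x$rate), sum(x$mask), x$overall_rate))
  invisible(x)
}

#' Gaussian smoothing kernel
#'
#' @param radius_bins Kernel radius in bins (support is a square of side
#'   `2 * radius + 1`); the default radius 2 gives a 5 x 5 kernel, radius 1
#'   the 3 x 3 variant.
#' @param sigma_bins Gaussian SD in bins.
#' @return Square matrix of kernel weights summing to 1.
#' @export
gaussian_kernel <- function(radius_bins = 2, sigma_bins = 1) {
  if (radius_bins < 0) stop("kernel radius must be >= 0")
  o <- -radius_bins:radius_bins
  k <- outer(o, o, function(a, b) exp(-(a^2 + b^2) / (2 * sigma_bins^2)))
  k / sum(k)
}

#' Smooth a rate map over its valid support
#'
#' Each valid pixel is replaced by the kernel-weighted mean of the valid
#' pixels under the kernel, with the weights renormalized over that valid
#' support; invalid pixels neither contribute to nor receive values. A
#' constant map is therefore unchanged and smoothing preserves positivity.
#'
#' @param map A `rate_map`.
#' @param kernel Kernel weight matrix, see [gaussian_kernel()].
#' @return A smoothed `rate_map` (same mask; `overall_rate` recomputed as the
#'   occupancy-weighted mean of the smoothed rates).
#' @export
smooth_rate_map <- function(map, kernel = gaussian_kernel()) {
  stopifnot(inherits(map, "rate_map"))
  if (!any(map$mask)) stop("no valid pixels to smooth")
  r <- (nrow(kernel) - 1L) / 2L
  n <- nrow(map$rate); m <- ncol(map$rate)
  z <- map$rate
  z[!map$mask] <- 0
  w <- matrix(0, n, m); w[map$mask] <- 1
  num <- matrix(0, n, m); den <- matrix(0, n, m)
  for (a in -r:r) {
    si <- max(1, 1 + a):min(n, n + a)   # destination rows
    oi <- si - a                        # source rows
    for (b in -r:r) {
      sj <- max(1, 1 + b):min(m, m + b)
      oj <- sj - b
      kw <- kernel[a + r + 1, b + r + 1]
      num[si, sj] <- num[si, sj] + kw * z[oi, oj]
      den[si, sj] <- den[si, sj] + kw * w[oi, oj]
    }
  }
  out <- matrix(NA_real_, n, m)
  out[map$mask] <- num[map$mask] / den[map$mask]
  map$rate <- out
  map$smoothed <- TRUE
  map$overall_rate <- sum(out[map$mask] * map$dwell[map$mask]) /
    sum(map$dwell[map$mask])
  map
}

#' Intersection of two maps' validity masks
#'
#' Between-session metrics (similarity, COM shift) only use pixels that pass
#' the occupancy criterion in both sessions.
#'
#' @param map_a,map_b `rate_map`s on the same grid.
#' @return Logical matrix, the intersection of the two masks.
#' @export
common_valid_mask <- function(map_a, map_b) {
  if (!identical(dim(map_a$rate), dim(map_b$rate)))
    stop("grid mismatch between maps")
  mask <- map_a$mask & map_b$mask
  if (!any(mask)) stop("no common valid pixels")
  mask
}

#' Restrict a rate map to a mask
#'
#' @param map A `rate_map`.
#' @param mask Logical matrix; pixels outside it become invalid.
#' @return The restricted `rate_map` (overall rate recomputed).
#' @export
restrict_rate_map <- function(map, mask) {
  keep <- map$mask & mask
  if (!any(keep)) stop("no valid pixels after restriction")
  map$rate[!keep] <- NA_real_
  map$mask <- keep
  map$overall_rate <- sum(map$rate[keep] * map$dwell[keep]) /
    sum(map$dwell[keep])
  map
}

#' Build occupancy, count, raw and smoothed rate maps in one call
#'
#' @param traj A `trajectory`.
#' @param spikes Numeric spike times, s.
#' @param arena An [arena_spec()].
#' @param min_occupancy Occupancy exclusion threshold, s.
#' @param kernel Smoothing kernel (see [gaussian_kernel()]).
#' @return List with `occupancy`, `counts`, `raw` and `smoothed` maps.
#' @export
rate_map_set <- function(traj, spikes, arena = arena_spec(),
                         min_occupancy = 0.1, kernel = gaussian_kernel()) {
  occ <- bin_occupancy(traj, arena)
  cnt <- bin_spikes(spikes, traj, arena)
  raw <- compute_rate_map(occ, cnt, min_occupancy)
  list(occupancy = occ, counts = cnt, raw = raw,
       smoothed = smooth_rate_map(raw, kernel))
}
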
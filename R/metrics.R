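#' Peak and mean firing rate of a rate map
#'
#' Peak rate is the maximum over valid pixels; mean rate is the
#' occupancy-weighted average over valid pixels (i.e. spikes per unit time
#' over the valid support).
#'
#' @param map A `rate_map`.
#' @return List of class `rate_summary` with `peak_hz` and `mean_hz`.
#' @export
summarize_rates <- function(map) {
  stopifnot(inherits(map, "rate_map"))
  if (!any(map$mask)) stop("no valid pixels")
  v <- map$rate[map$mask]
  w <- map$dwell[map$mask]
  structure(list(peak_hz = max(v), mean_hz = sum(v * w) / sum(w)),
            class = "rate_summary")
}

#' Skaggs spatial information of a rate map
#'
#' Computes the information rate `I(R|X) = sum_i p_i f_i log2(f_i / F)` over
#' valid pixels, where `p_i` is the occupancy probability of pixel i, `f_i`
#' its firing rate and `F = sum_i p_i f_i` the overall rate, with the
#' convention `0 * log 0 = 0`. The headline value is bits per spike
#' (rate divided by `F`), the unit in which place-cell SI is reported.
#'
#' @param map A `rate_map` (typically smoothed).
#' @return List of class `si_result`: `bits_per_second`, `bits_per_spike`,
#'   `overall_rate`.
#' @export
spatial_information <- function(map) {
  stopifnot(inherits(map, "rate_map"))
  if (!any(map$mask)) stop("no valid pixels")
  f <- map$rate[map$mask]
  w <- map$dwell[map$mask]
  p <- w / sum(w)
  FF <- sum(p * f)
  if (FF <= 0) stop("silent unit: overall rate is zero, SI undefined")
  term <- ifelse(f > 0, p * f * log2(f / FF), 0)
  bps <- sum(term)
  structure(list(bits_per_second = bps, bits_per_spike = bps / FF,
                 overall_rate = FF),
            class = "si_result")
}

# 4-connected component labelling by flood fill over a logical matrix.
label_components <- function(mask) {
  n <- nrow(mask); m <- ncol(mask)
  lab <- matrix(0L, n, m)
  cur <- 0L
  for (start in which(mask & lab == 0L)) {
    cur <- cur + 1L
    stack <- start
    while (length(stack)) {
      p <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (lab[p] != 0L || !mask[p]) next
      lab[p] <- cur
      i <- (p - 1L) %% n + 1L; j <- (p - 1L) %/% n + 1L
      if (i > 1L) stack <- c(stack, p - 1L)
      if (i < n) stack <- c(stack, p + 1L)
      if (j > 1L) stack <- c(stack, p - n)
      if (j < m) stack <- c(stack, p + n)
    }
  }
  lab
}

#' Detect the place field of a rate map
#'
#' A place field is the set of at least `min_pixels` edge-sharing
#' (4-connected) pixels with rate at or above `threshold_frac` of the peak
#' rate that contains the peak pixel; suprathreshold regions that do not
#' contain the peak are discarded. Field size is the pixel count times the
#' pixel area.
#'
#' @param map A `rate_map` (typically smoothed).
#' @param threshold_frac Rate threshold as a fraction of peak (default 0.1).
#' @param min_pixels Minimum component size (default 8).
#' @return Object of class `place_field` (`pixels` two-column matrix of bin
#'   indices, `n_pixels`, `size_cm2`, `peak_pixel`, `peak_rate`) or `NULL`
#'   when no qualifying field exists (including an all-zero map).
#' @export
detect_place_field <- function(map, threshold_frac = 0.1, min_pixels = 8) {
  stopifnot(inherits(map, "rate_map"))
  if (!any(map$mask)) stop("no valid pixels")
  r <- map$rate
  peak <- max(r[map$mask])
  if (peak <= 0) return(NULL)
  supra <- map$mask & !is.na(r) & r >= threshold_frac * peak
  lab <- label_components(supra)
  peak_idx <- which(map$mask & !is.na(r) & r == peak)[1]
  field_lab <- lab[peak_idx]
  px <- which(lab == field_lab)
  if (length(px) < min_pixels) return(NULL)
  n <- nrow(r)
  pixels <- cbind(ix = (px - 1L) %% n + 1L, iy = (px - 1L) %/% n + 1L)
  structure(list(pixels = pixels, n_pixels = length(px),
                 size_cm2 = length(px) * map$arena$bin_size^2,
                 peak_pixel = c(ix = (peak_idx - 1L) %% n + 1L,
                                iy = (peak_idx - 1L) %/% n + 1L),
                 peak_rate = peak),
            class = "place_field")
}

#' @export
print.place_field <- function(x, ...) {
  cat(sprintf("<place_field> %d pixels, %.0f cm^2, peak %.2f Hz at (%d, %d)\n",
              x$n_pixels, x$size_cm2, x$peak_rate,
              x$peak_pixel["ix"], x$peak_pixel["iy"]))
  invisible(x)
}

#' Rate-weighted center of mass
#'
#' The COM is the firing-rate-weighted mean of pixel-center coordinates,
#' either over the whole valid map or restricted to the detected place field.
#' The default scope is field-restricted when a field exists, falling back to
#' the full map; the scope used is recorded on the result.
#'
#' @param map A `rate_map`.
#' @param scope "auto" (field if present, else full map), "field" or "full".
#' @param field Optional pre-computed [detect_place_field()] result.
#' @return Numeric (x, y) in cm with attribute `scope`.
#' @export
center_of_mass <- function(map, scope = c("auto", "field", "full"),
                           field = NULL) {
  scope <- match.arg(scope)
  stopifnot(inherits(map, "rate_map"))
  if (scope != "full" && is.null(field)) field <- detect_place_field(map)
  use_field <- switch(scope,
                      full = FALSE,
                      field = { if (is.null(field)) stop("no place field"); TRUE },
                      auto = !is.null(field))
  if (use_field) {
    ix <- field$pixels[, "ix"]; iy <- field$pixels[, "iy"]
    wgt <- map$rate[cbind(ix, iy)]
  } else {
    idx <- which(map$mask & !is.na(map$rate))
    n <- nrow(map$rate)
    ix <- (idx - 1L) %% n + 1L; iy <- (idx - 1L) %/% n + 1L
    wgt <- map$rate[idx]
  }
  if (sum(wgt) <= 0) stop("zero total rate in COM scope")
  ctr <- pixel_centers(ix, iy, map$arena)
  out <- c(x = sum(ctr[, "x"] * wgt) / sum(wgt),
           y = sum(ctr[, "y"] * wgt) / sum(wgt))
  attr(out, "scope") <- if (use_field) "field" else "full"
  out
}

#' Between-trial shift of the center of mass
#'
#' Both maps are restricted to their common valid mask; each COM is then
#' computed (field-restricted where a field exists) and the shift is the
#' Euclidean distance between them, with the displacement reported as the COM
#' vector `COM_B - COM_A`.
#'
#' @param map_a,map_b `rate_map`s of the same unit in two trials.
#' @param scope COM scope passed to [center_of_mass()].
#' @return List: `distance_cm`, `vector` (dx, dy), `com_a`, `com_b`.
#' @export
com_shift <- function(map_a, map_b, scope = "auto") {
  mask <- common_valid_mask(map_a, map_b)
  a <- center_of_mass(restrict_rate_map(map_a, mask), scope)
  b <- center_of_mass(restrict_rate_map(map_b, mask), scope)
  v <- c(b["x"] - a["x"], b["y"] - a["y"])
  names(v) <- c("dx", "dy")
  list(distance_cm = sqrt(sum(v^2)), vector = v, com_a = a, com_b = b)
}

#' Similarity score between two rate maps
#'
#' Pearson product-moment correlation between the per-pixel rates of the two
#' maps over their common valid pixels.
#'
#' @param map_a,map_b `rate_map`s on the same grid.
#' @return Correlation in `[-1, 1]`, or `NA` with attribute `reason` when
#'   undefined (fewer than 3 common pixels or a map constant on the mask).
#' @export
similarity_score <- function(map_a, map_b) {
  mask <- common_valid_mask(map_a, map_b)
  a <- map_a$rate[mask]; b <- map_b$rate[mask]
  if (length(a) < 3)
    return(structure(NA_real_, reason = "fewer than 3 common valid pixels"))
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    return(structure(NA_real_, reason = "constant map on common mask"))
  stats::cor(a, b)
}

#' Distance from a COM to the nearest object
#'
#' @param com Numeric (x, y), cm (e.g. from [center_of_mass()]).
#' @param layout An [object_layout()].
#' @param trial Which trial's objects to use ("T2" or "T3").
#' @return List: `label` (character; two labels on an exact tie),
#'   `distance_cm`.
#' @export
object_proximity <- function(com, layout, trial = "T2") {
  obj <- trial_objects(layout, trial)
  if (nrow(obj) == 0L) stop("no objects in layout for this trial")
  d <- sqrt((com[["x"]] - obj$x)^2 + (com[["y"]] - obj$y)^2)
  dmin <- min(d)
  list(label = obj$label[abs(d - dmin) < 1e-9], distance_cm = dmin)
}

#' Screen a unit by waveform width and refractory gap
#'
#' Units with a clear autocorrelogram refractory gap are putative pyramidal
#' cells when the peak-to-trough spike width is at least 250 microseconds and
#' putative interneurons when narrower; units without a refractory gap, or
#' without waveform metadata, are rejected.
#'
#' @param spike_width_us Peak-to-trough width, microseconds (`NA` if unknown).
#' @param has_refractory_gap Logical.
#' @return One of "putative_pyramidal", "putative_interneuron", "rejected",
#'   with attribute `reason` when rejected.
#' @export
screen_unit <- function(spike_width_us, has_refractory_gap) {
  if (is.na(spike_width_us))
    return(structure("rejected", reason = "no waveform metadata"))
  if (spike_width_us <= 0) stop("spike width must be positive")
  if (!isTRUE(has_refractory_gap))
    return(structure("rejected", reason = "no refractory gap"))
  if (spike_width_us >= 250) "putative_pyramidal" else "putative_interneuron"
}
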
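#' Square arena specification
#'
#' Defines the recording arena: a square box with its south-west corner at
#' (0, 0), x increasing eastward and y increasing northward, discretized into
#' square pixels for rate-map analysis. The default is a 40-cm box on a
#' 20 x 20 grid of 2-cm pixels.
#'
#' @param side_length Side of the square arena in cm.
#' @param bin_size Pixel side in cm; must divide `side_length` exactly.
#' @return An object of class `arena_spec` with fields `side_length`,
#'   `bin_size` and `n_bins` (pixels per axis).
#' @examples
#' arena_spec()            # 40 cm, 2-cm pixels, 20 x 20 grid
#' arena_spec(60, 3)
#' @export
arena_spec <- function(side_length = 40, bin_size = 2) {
  if (!is.numeric(side_length) || length(side_length) != 1L || side_length <= 0)
    stop("side_length must be a single positive number")
  if (!is.numeric(bin_size) || length(bin_size) != 1L || bin_size <= 0)
    stop("bin_size must be a single positive number")
  n <- side_length / bin_size
  if (abs(n - round(n)) > 1e-9)
    stop("side_length must be divisible by bin_size")
  structure(
    list(side_length = side_length, bin_size = bin_size, n_bins = as.integer(round(n))),
    class = "arena_spec"
  )
}

#' @export
print.arena_spec <- function(x, ...) {
  cat(sprintf("<arena_spec> %g cm square, %d x %d grid of %g-cm pixels\n",
              x$side_length, x$n_bins, x$n_bins, x$bin_size))
  invisible(x)
}

#' Quadrant centers of the arena
#'
#' Object sites in the OPM task are the centers of the four quadrants: for a
#' 40-cm arena these lie 10 cm from the two near walls.
#'
#' @param arena An [arena_spec()].
#' @return A 4 x 2 matrix of (x, y) in cm with rownames SW, SE, NW, NE.
#' @export
quadrant_centers <- function(arena = arena_spec()) {
  s <- arena$side_length
  m <- rbind(SW = c(s / 4, s / 4),
             SE = c(3 * s / 4, s / 4),
             NW = c(s / 4, 3 * s / 4),
             NE = c(3 * s / 4, 3 * s / 4))
  colnames(m) <- c("x", "y")
  m
}

#' Arena center point
#' @param arena An [arena_spec()].
#' @return Numeric (x, y) in cm.
#' @export
arena_center <- function(arena = arena_spec()) {
  c(x = arena$side_length / 2, y = arena$side_length / 2)
}

is_inside_arena <- function(x, y, arena) {
  x >= 0 & x <= arena$side_length & y >= 0 & y <= arena$side_length
}

#' Map coordinates to pixel indices
#'
#' Bins are half-open `[i*bin, (i+1)*bin)` with the last bin closed, so an
#' interior point sitting exactly on a bin edge belongs to the higher bin and
#' points on the far wall belong to the last bin.
#'
#' @param v Numeric coordinates in cm (one axis).
#' @param arena An [arena_spec()].
#' @return Integer bin indices in `1..n_bins`.
#' @export
bin_index <- function(v, arena = arena_spec()) {
  if (any(v < 0 | v > arena$side_length))
    stop("coordinates outside the arena")
  i <- floor(v / arena$bin_size) + 1
  i[i > arena$n_bins] <- arena$n_bins
  as.integer(i)
}

#' Pixel center coordinates
#'
#' @param ix,iy Integer bin indices (x and y axes).
#' @param arena An [arena_spec()].
#' @return Matrix with columns x, y (cm).
#' @export
pixel_centers <- function(ix, iy, arena = arena_spec()) {
  cbind(x = (ix - 0.5) * arena$bin_size, y = (iy - 0.5) * arena$bin_size)
}

#' Object layout for the OPM task
#'
#' Two identical objects are placed at quadrant centers for the sample trial
#' (T2); for the choice trial (T3) one object stays put ("stable") and the
#' other moves to the adjacent quadrant center ("moved"), a 20-cm displacement
#' in the default arena. Each object carries a circular interaction zone whose
#' diameter is the object base diameter plus twice the snout-proximity
#' threshold (4.5 + 2 x 1 = 6.5 cm by default).
#'
#' @param sites Character(2), quadrant labels of the two T2 objects
#'   (among "SW", "SE", "NW", "NE").
#' @param moved_site Which of `sites` moves on T3.
#' @param dest_site Destination quadrant (must be adjacent, i.e. share a side
#'   with `moved_site`, and be empty).
#' @param base_diameter Object base diameter, cm.
#' @param proximity_cm Snout proximity threshold added around the object, cm.
#' @param arena An [arena_spec()].
#' @return Object of class `object_layout`: `objects` (data.frame with trial,
#'   label, site, x, y, base_diameter, zone_diameter), `move_vector` (dx, dy)
#'   and `arena`.
#' @export
object_layout <- function(sites = c("NW", "NE"), moved_site = "NE",
                          dest_site = "SE", base_diameter = 4.5,
                          proximity_cm = 1, arena = arena_spec()) {
  qc <- quadrant_centers(arena)
  sites <- match.arg(sites, rownames(qc), several.ok = TRUE)
  if (length(sites) != 2L || anyDuplicated(sites))
    stop("sites must name two distinct quadrants")
  if (!moved_site %in% sites) stop("moved_site must be one of sites")
  if (dest_site %in% sites) stop("dest_site must be an empty quadrant")
  mv <- qc[dest_site, ] - qc[moved_site, ]
  if (abs(sqrt(sum(mv^2)) - arena$side_length / 2) > 1e-9)
    stop("dest_site must be adjacent to moved_site (sharing a side)")
  zone <- base_diameter + 2 * proximity_cm
  stable_site <- setdiff(sites, moved_site)

  lr <- function(site) if (qc[site, "x"] > arena$side_length / 2) "right" else "left"
  t2 <- data.frame(trial = "T2", label = vapply(sites, lr, ""), site = sites,
                   x = qc[sites, "x"], y = qc[sites, "y"],
                   stringsAsFactors = FALSE)
  t3 <- data.frame(trial = "T3",
                   label = c("stable", "moved"),
                   site = c(stable_site, dest_site),
                   x = c(qc[stable_site, "x"], qc[dest_site, "x"]),
                   y = c(qc[stable_site, "y"], qc[dest_site, "y"]),
                   stringsAsFactors = FALSE)
  objects <- rbind(t2, t3)
  objects$base_diameter <- base_diameter
  objects$zone_diameter <- zone
  rownames(objects) <- NULL
  structure(list(objects = objects, move_vector = unname(mv),
                 moved_site = moved_site, dest_site = dest_site,
                 arena = arena),
            class = "object_layout")
}

#' @export
print.object_layout <- function(x, ...) {
  cat("<object_layout>\n")
  print(x$objects)
  cat(sprintf("move vector: (%g, %g) cm\n", x$move_vector[1], x$move_vector[2]))
  invisible(x)
}

#' Objects present in a given trial
#' @param layout An [object_layout()].
#' @param trial "T2" or "T3" ("T1" returns an empty frame).
#' @return data.frame of object records.
#' @export
trial_objects <- function(layout, trial) {
  layout$objects[layout$objects$trial == trial, , drop = FALSE]
}
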
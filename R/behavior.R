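#' Detect object-visit episodes from a nose track
#'
#' A visit episode is a maximal run of frames in which the nose is inside an
#' object's circular zone (zone radius = base radius + snout-proximity
#' threshold; 6.5-cm zone diameter for the default 4.5-cm objects).
#'
#' @param traj A `trajectory` of nose positions.
#' @param layout An [object_layout()].
#' @param trial Which trial's objects to score ("T2" or "T3").
#' @param min_episode_frames Minimum episode length in frames (default 1).
#' @return data.frame of class `visit_episodes`: `object`, `start_s`,
#'   `end_s`, `duration_s` (zero rows when there are no visits).
#' @export
detect_object_visits <- function(traj, layout, trial = "T2",
                                 min_episode_frames = 1) {
  obj <- trial_objects(layout, trial)
  if (nrow(obj) == 0L) stop("no objects in layout for this trial")
  radius <- obj$zone_diameter / 2
  if (nrow(obj) > 1) {
    dc <- sqrt((obj$x[1] - obj$x[2])^2 + (obj$y[1] - obj$y[2])^2)
    if (dc < sum(radius)) stop("object zones overlap: ambiguous assignment")
  }
  fp <- 1 / attr(traj, "frame_rate")
  out <- list()
  for (k in seq_len(nrow(obj))) {
    inside <- sqrt((traj$x_cm - obj$x[k])^2 + (traj$y_cm - obj$y[k])^2) <=
      radius[k]
    r <- rle(inside)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & r$lengths >= min_episode_frames
    if (any(keep))
      out[[obj$label[k]]] <- data.frame(
        object = obj$label[k],
        start_s = traj$time_s[starts[keep]],
        end_s = traj$time_s[ends[keep]] + fp,
        duration_s = r$lengths[keep] * fp,
        stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(object = character(0), start_s = numeric(0),
               end_s = numeric(0), duration_s = numeric(0))
  rownames(res) <- NULL
  class(res) <- c("visit_episodes", "data.frame")
  res
}

#' Summarize visits per object
#' @param episodes A `visit_episodes` data.frame.
#' @param objects Character vector of object labels to report (defaults to
#'   those present).
#' @return data.frame: `object`, `n_visits`, `total_s`.
#' @export
summarize_visits <- function(episodes, objects = unique(episodes$object)) {
  data.frame(
    object = objects,
    n_visits = vapply(objects, function(o) sum(episodes$object == o), 0L),
    total_s = vapply(objects, function(o)
      sum(episodes$duration_s[episodes$object == o]), 0),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Exploration ratio on the sample trial
#'
#' Returns both conventions for the two-object sample trial: the quotient
#' form `R / (L + R)` in `[0, 1]` and the discrimination form
#' `(R - L) / (L + R)` in `[-1, 1]`. The discrimination form is the headline
#' value (group means of this index can be negative, which the quotient form
#' cannot produce).
#'
#' @param time_left,time_right Exploration time of the left and right
#'   objects, s.
#' @return List: `quotient`, `discrimination`; both `NA` with a `reason`
#'   attribute when no object was explored.
#' @export
exploration_ratio <- function(time_left, time_right) {
  tot <- time_left + time_right
  if (tot <= 0)
    return(structure(list(quotient = NA_real_, discrimination = NA_real_),
                     reason = "no object exploration"))
  list(quotient = time_right / tot,
       discrimination = (time_right - time_left) / tot)
}

#' OPM discrimination ratio on the choice trial
#'
#' `(moved - stable) / (moved + stable)`: positive values indicate
#' preferential exploration of the displaced object.
#'
#' @param time_moved,time_stable Exploration time of the moved and stable
#'   objects, s.
#' @return Ratio in `[-1, 1]`, or `NA` with a `reason` attribute when no
#'   object was explored.
#' @export
opm_ratio <- function(time_moved, time_stable) {
  tot <- time_moved + time_stable
  if (tot <= 0)
    return(structure(NA_real_, reason = "no object exploration"))
  (time_moved - time_stable) / tot
}

#' Percent of time spent moving
#'
#' Fraction of frame intervals whose instantaneous speed is at or above the
#' movement threshold, times 100.
#'
#' @param traj A `trajectory` (at least 2 frames).
#' @param speed_threshold Movement threshold, cm/s (default 2, a standard
#'   rodent immobility cutoff).
#' @return Percentage in `[0, 100]`.
#' @export
percent_time_moving <- function(traj, speed_threshold = 2) {
  if (nrow(traj) < 2) stop("trajectory must have at least 2 frames")
  sp <- trajectory_speed(traj)
  100 * mean(sp >= speed_threshold)
}

#' Behavioral summary of an OPM session
#'
#' Scores object visits on T2 and T3, the exploration and OPM discrimination
#' ratios, and percent time moving per trial.
#'
#' @param session An `opm_session` (or any list with `trajectories` and
#'   `manifest$layout`).
#' @param speed_threshold Movement threshold, cm/s.
#' @param min_episode_frames Minimum visit-episode length, frames.
#' @return List: `visits` (per trial x object), `exploration_ratio`
#'   (quotient), `exploration_di` (discrimination form), `opm_ratio`,
#'   `pct_moving` (named per trial).
#' @export
score_behavior <- function(session, speed_threshold = 2,
                           min_episode_frames = 1) {
  layout <- session$manifest$layout
  vis <- list()
  for (tr in c("T2", "T3")) {
    ep <- detect_object_visits(session$trajectories[[tr]], layout, tr,
                               min_episode_frames)
    sv <- summarize_visits(ep, trial_objects(layout, tr)$label)
    sv$trial <- tr
    vis[[tr]] <- sv
  }
  visits <- do.call(rbind, vis)
  rownames(visits) <- NULL
  t2 <- vis$T2; t3 <- vis$T3
  er <- exploration_ratio(t2$total_s[t2$object == "left"],
                          t2$total_s[t2$object == "right"])
  om <- opm_ratio(t3$total_s[t3$object == "moved"],
                  t3$total_s[t3$object == "stable"])
  pct <- vapply(session$trajectories, percent_time_moving,
                0, speed_threshold = speed_threshold)
  list(visits = visits, exploration_ratio = er$quotient,
       exploration_di = er$discrimination, opm_ratio = as.numeric(om),
       pct_moving = pct)
}
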
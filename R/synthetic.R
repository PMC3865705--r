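#' Gaussian place-tuning specification
#'
#' A unit's spatial tuning is a 2-D circular Gaussian bump over the arena:
#' `rate(p) = baseline + (peak - baseline) * exp(-d^2 / (2 sigma^2))` with
#' `d` the distance from `p` to the tuning center. Units with peak rates
#' below the 3-Hz activity boundary model "inactive" cells.
#'
#' @param center Numeric (x, y) tuning center, cm; must lie inside the arena.
#' @param sigma Tuning width (Gaussian SD), cm; > 0.
#' @param peak Rate at the center, Hz.
#' @param baseline Floor rate far from the center, Hz.
#' @param dynamics Free-form tag recording the unit's across-trial plan.
#' @param arena An [arena_spec()] used to validate the center.
#' @return Object of class `tuning_spec`.
#' @export
tuning_spec <- function(center, sigma, peak, baseline = 0,
                        dynamics = "stable", arena = arena_spec()) {
  center <- as.numeric(center)
  if (length(center) != 2L || !all(is_inside_arena(center[1], center[2], arena)))
    stop("tuning center must be a point inside the arena")
  if (sigma <= 0) stop("sigma must be > 0")
  if (baseline < 0 || peak < baseline)
    stop("need peak >= baseline >= 0")
  structure(list(center = center, sigma = sigma, peak = peak,
                 baseline = baseline, dynamics = dynamics),
            class = "tuning_spec")
}

#' Evaluate a tuning curve at positions
#'
#' @param spec A [tuning_spec()].
#' @param x,y Positions in cm (vectors of equal length).
#' @param arena An [arena_spec()]; positions must be inside.
#' @return Firing rate(s), Hz.
#' @export
evaluate_tuning <- function(spec, x, y, arena = arena_spec()) {
  if (any(!is_inside_arena(x, y, arena)))
    stop("position outside the arena")
  d2 <- (x - spec$center[1])^2 + (y - spec$center[2])^2
  spec$baseline + (spec$peak - spec$baseline) * exp(-d2 / (2 * spec$sigma^2))
}

#' Condition (drug) effect on place tuning
#'
#' Models the qualitative effect of systemic NMDAR antagonism (CPP) on place
#' fields: wider tuning, mildly attenuated peaks, and tuning centers pulled
#' toward the arena center. The saline (SAL) control is the identity effect.
#'
#' @param condition "SAL" or "CPP".
#' @param width_multiplier Multiplies the tuning sigma (> 0).
#' @param peak_attenuation Scales the above-baseline peak amplitude, in (0, 1].
#' @param com_pull_to_center Fraction of the center-to-arena-center vector
#'   applied to the tuning center, in `[0, 1]`.
#' @return Object of class `condition_effect`.
#' @export
condition_effect <- function(condition = c("SAL", "CPP"),
                             width_multiplier = if (condition == "CPP") 1.8 else 1,
                             peak_attenuation = if (condition == "CPP") 0.8 else 1,
                             com_pull_to_center = if (condition == "CPP") 0.4 else 0) {
  condition <- match.arg(condition)
  if (width_multiplier <= 0) stop("width_multiplier must be > 0")
  if (peak_attenuation <= 0 || peak_attenuation > 1)
    stop("peak_attenuation must be in (0, 1]")
  if (com_pull_to_center < 0 || com_pull_to_center > 1)
    stop("com_pull_to_center must be in [0, 1]")
  if (condition == "SAL" &&
      (width_multiplier != 1 || peak_attenuation != 1 || com_pull_to_center != 0))
    stop("SAL is the identity effect")
  structure(list(condition = condition, width_multiplier = width_multiplier,
                 peak_attenuation = peak_attenuation,
                 com_pull_to_center = com_pull_to_center),
            class = "condition_effect")
}

#' Apply a condition effect to a tuning spec
#'
#' @param spec A [tuning_spec()].
#' @param effect A [condition_effect()].
#' @param arena An [arena_spec()].
#' @return The perturbed `tuning_spec` (unchanged for SAL).
#' @export
apply_condition <- function(spec, effect, arena = arena_spec()) {
  stopifnot(inherits(spec, "tuning_spec"), inherits(effect, "condition_effect"))
  if (effect$condition == "SAL") return(spec)
  ctr <- arena_center(arena)
  new_center <- spec$center + effect$com_pull_to_center * (ctr - spec$center)
  tuning_spec(center = new_center,
              sigma = spec$sigma * effect$width_multiplier,
              peak = spec$baseline +
                (spec$peak - spec$baseline) * effect$peak_attenuation,
              baseline = spec$baseline,
              dynamics = spec$dynamics, arena = arena)
}

#' Default locomotion parameters
#'
#' Persistent random walk with a two-state move/pause process. `mean_speed`
#' is the target mean of the *overall* speed distribution (pauses included);
#' the moving-state speed is scaled up by the expected moving fraction so the
#' overall mean comes out near the target.
#'
#' @param mean_speed Overall mean speed, cm/s.
#' @param turn_sd Heading diffusion, rad per sqrt(s).
#' @param p_pause,p_unpause Per-frame move->pause / pause->move switching
#'   probabilities (at 30 Hz).
#' @param wall_margin Distance from a wall (cm) at which heading is steered
#'   back toward the arena center.
#' @param wall_gain Steering gain in the wall zone, per frame, in `[0, 1]`.
#' @return Named list of motion parameters.
#' @export
motion_params <- function(mean_speed = 5, turn_sd = 1.2,
                          p_pause = 0.01, p_unpause = 0.02,
                          wall_margin = 3, wall_gain = 0.2) {
  list(mean_speed = mean_speed, turn_sd = turn_sd, p_pause = p_pause,
       p_unpause = p_unpause, wall_margin = wall_margin, wall_gain = wall_gain)
}

#' Simulate a confined random-walk trajectory
#'
#' Generates a nose-position track at fixed frame rate inside the arena:
#' a persistent random walk (slowly diffusing heading, Ornstein-Uhlenbeck-like
#' speed) with reflective walls, wall-avoiding steering, and a two-state
#' move/pause process. Optionally the walk slows inside object zones to model
#' dwell bias near objects.
#'
#' @param duration Trial duration, s (> 0).
#' @param arena An [arena_spec()].
#' @param frame_rate Sampling rate, Hz (default 30).
#' @param motion A [motion_params()] list.
#' @param object_bias Optional list `list(layout =, trial =, dwell_gain =)`;
#'   inside an object zone the moving speed is divided by `dwell_gain` (> 1
#'   biases dwell toward objects). `NULL` (default) disables the bias.
#' @param seed Integer RNG seed.
#' @param t0 Session time of the first frame, s.
#' @return A data.frame of class `trajectory` with columns `time_s`, `x_cm`,
#'   `y_cm` and attributes `frame_rate` and `arena`.
#' @export
generate_trajectory <- function(duration, arena = arena_spec(), frame_rate = 30,
                                motion = motion_params(), object_bias = NULL,
                                seed = 1, t0 = 0) {
  if (!is.numeric(duration) || duration <= 0) stop("duration must be > 0")
  if (!is.numeric(frame_rate) || frame_rate <= 0) stop("frame_rate must be > 0")
  local_seed(seed)
  dt <- 1 / frame_rate
  n <- as.integer(round(duration * frame_rate))
  side <- arena$side_length
  f_move <- motion$p_unpause / (motion$p_pause + motion$p_unpause)
  v_move <- motion$mean_speed / f_move   # moving-state mean speed
  v_pause <- 0.3                         # residual jitter while paused

  x <- y <- numeric(n)
  x[1] <- stats::runif(1, side * 0.25, side * 0.75)
  y[1] <- stats::runif(1, side * 0.25, side * 0.75)
  theta <- stats::runif(1, 0, 2 * pi)
  v <- v_move
  moving <- TRUE
  eps <- 1e-6

  obj <- NULL
  if (!is.null(object_bias)) {
    ob <- trial_objects(object_bias$layout, object_bias$trial)
    obj <- list(x = ob$x, y = ob$y, r = ob$zone_diameter / 2,
                gain = object_bias$dwell_gain)
  }

  turns <- stats::rnorm(n, 0, motion$turn_sd * sqrt(dt))
  u_state <- stats::runif(n)
  v_noise <- stats::rnorm(n, 0, 1)

  for (i in seq_len(n)[-1]) {
    # move/pause switching
    if (moving && u_state[i] < motion$p_pause) moving <- FALSE
    else if (!moving && u_state[i] < motion$p_unpause) moving <- TRUE
    target_v <- if (moving) v_move else v_pause
    v <- max(0, v + 0.2 * (target_v - v) + 0.3 * sqrt(target_v) * v_noise[i])
    sp <- v
    if (!is.null(obj) && moving) {
      d <- sqrt((x[i - 1] - obj$x)^2 + (y[i - 1] - obj$y)^2)
      if (any(d <= obj$r)) sp <- sp / obj$gain
    }
    # wall-avoiding steering: rotate heading toward the arena center
    dx_w <- min(x[i - 1], side - x[i - 1])
    dy_w <- min(y[i - 1], side - y[i - 1])
    if (min(dx_w, dy_w) < motion$wall_margin) {
      to_ctr <- atan2(side / 2 - y[i - 1], side / 2 - x[i - 1])
      dtheta <- atan2(sin(to_ctr - theta), cos(to_ctr - theta))
      theta <- theta + motion$wall_gain * dtheta
    }
    theta <- theta + turns[i]
    xn <- x[i - 1] + sp * dt * cos(theta)
    yn <- y[i - 1] + sp * dt * sin(theta)
    # reflective walls (preserves step length)
    if (xn < 0) { xn <- -xn; theta <- pi - theta }
    if (xn > side) { xn <- 2 * side - xn; theta <- pi - theta }
    if (yn < 0) { yn <- -yn; theta <- -theta }
    if (yn > side) { yn <- 2 * side - yn; theta <- -theta }
    x[i] <- min(max(xn, eps), side - eps)
    y[i] <- min(max(yn, eps), side - eps)
  }

  out <- data.frame(time_s = t0 + (seq_len(n) - 1) * dt, x_cm = x, y_cm = y)
  attr(out, "frame_rate") <- frame_rate
  attr(out, "arena") <- arena
  class(out) <- c("trajectory", "data.frame")
  out
}

#' Instantaneous speed of a trajectory
#' @param traj A `trajectory`.
#' @return Numeric vector of per-interval speeds, cm/s (length `nrow - 1`).
#' @export
trajectory_speed <- function(traj) {
  dx <- diff(traj$x_cm); dy <- diff(traj$y_cm); dtt <- diff(traj$time_s)
  sqrt(dx^2 + dy^2) / dtt
}

#' Simulate spikes from a tuned unit along a trajectory
#'
#' Inhomogeneous-Poisson spiking by thinning: candidate events are drawn from
#' a homogeneous Poisson process at the tuning's maximum rate and accepted
#' with probability `rate(position(t)) / max_rate`, with positions looked up
#' at the temporally nearest video frame.
#'
#' @param spec A [tuning_spec()].
#' @param traj A `trajectory` from [generate_trajectory()].
#' @param seed Integer RNG seed.
#' @param arena An [arena_spec()].
#' @return Sorted numeric vector of spike times, s (possibly empty).
#' @export
simulate_spikes <- function(spec, traj, seed = 1, arena = arena_spec()) {
  if (nrow(traj) == 0L) stop("trajectory is empty")
  local_seed(seed)
  lambda_max <- spec$peak
  t0 <- traj$time_s[1]
  t1 <- traj$time_s[nrow(traj)]
  span <- t1 - t0
  if (lambda_max <= 0 || span <= 0) return(numeric(0))
  n_cand <- stats::rpois(1, lambda_max * span)
  if (n_cand == 0L) return(numeric(0))
  tt <- sort(stats::runif(n_cand, t0, t1))
  fr <- attr(traj, "frame_rate")
  idx <- pmin(pmax(round((tt - t0) * fr) + 1, 1), nrow(traj))
  lam <- evaluate_tuning(spec, traj$x_cm[idx], traj$y_cm[idx], arena)
  tt[stats::runif(n_cand) < lam / lambda_max]
}

#' Default class-dynamics probabilities per trial transition
#'
#' Probabilities over the five generator classes (stable, unstable, emerging,
#' vanishing, inactive) for the T1->T2 and T2->T3 transitions. Defaults echo
#' the observed cohort composition in saline sessions: ~59% active on T1->T2
#' with ~20% emerging, ~67% active on T2->T3 with few emerging. The T2->T3
#' vector is renormalized per unit over the classes consistent with that
#' unit's activity state at the end of T2.
#'
#' @param t1_t2,t2_t3 Named numeric vectors summing to 1 over
#'   `c("stable", "unstable", "emerging", "vanishing", "inactive")`.
#' @return List with elements `t1_t2` and `t2_t3`.
#' @export
class_probs <- function(
    t1_t2 = c(stable = 0.44, unstable = 0.15, emerging = 0.20,
              vanishing = 0.10, inactive = 0.11),
    t2_t3 = c(stable = 0.49, unstable = 0.18, emerging = 0.07,
              vanishing = 0.09, inactive = 0.17)) {
  for (p in list(t1_t2, t2_t3)) {
    if (!all(c("stable", "unstable", "emerging", "vanishing", "inactive")
             %in% names(p)))
      stop("class probabilities must name all five classes")
    if (any(p < 0) || any(p > 1)) stop("probabilities must lie in [0, 1]")
    if (abs(sum(p) - 1) > 1e-6)
      stop("class probabilities must sum to 1 per transition")
  }
  list(t1_t2 = t1_t2, t2_t3 = t2_t3)
}

.trial_table <- function() {
  data.frame(trial = c("T1", "T2", "T3"),
             start_s = c(0, 1500, 2400),
             end_s = c(900, 1800, 2700),
             stringsAsFactors = FALSE)
}

# Draw one active-unit tuning (lognormal peaks >= 3 Hz) or an inactive one
# (sub-3-Hz peak). Consumes the current RNG stream.
# Centers keep a 1.5-sigma wall margin: a Gaussian field clipped by a wall
# has a genuinely displaced centroid, which would make the generator's
# "tuning center" ill-defined as a ground truth for COM recovery.
.draw_tuning <- function(active, arena) {
  side <- arena$side_length
  if (active) {
    peak <- 3 + stats::rlnorm(1, meanlog = log(6), sdlog = 0.6)
    sigma <- stats::runif(1, 3, 5.5)
  } else {
    peak <- stats::runif(1, 0.3, 2.5)
    sigma <- stats::runif(1, 4, 8)
  }
  margin <- max(4, 1.5 * sigma)
  ctr <- stats::runif(2, margin, side - margin)
  # out-of-field rate stays well below the 10%-of-peak field threshold,
  # as in real pyramidal cells
  baseline <- stats::runif(1, 0, min(0.3, 0.05 * peak))
  tuning_spec(ctr, sigma, peak, baseline, arena = arena)
}

# Displace an unstable unit's tuning center for the next trial.
# For T2->T3 the default rule mirrors the object-vector observation: units
# whose T2 center is near the moving object follow the object's displacement
# vector; far units move against it. For T1->T2 (no object move yet) the
# displacement direction is isotropic.
.displace_center <- function(center, rule, layout, transition, arena) {
  side <- arena$side_length
  mag <- stats::runif(1, rule$mag_cm[1], rule$mag_cm[2])
  if (transition == "t2_t3" && !is.null(layout)) {
    qc <- quadrant_centers(arena)
    obj_t2 <- qc[layout$moved_site, ]
    mv <- layout$move_vector
    u <- mv / sqrt(sum(mv^2))
    d <- sqrt(sum((center - obj_t2)^2))
    if (d < rule$near_cm) disp <- mv else disp <- -u * mag
  } else {
    ang <- stats::runif(1, 0, 2 * pi)
    disp <- mag * c(cos(ang), sin(ang))
  }
  disp <- disp + stats::rnorm(2, 0, rule$jitter_cm)
  pmin(pmax(center + disp, 2), side - 2)
}

#' Default unstable-unit displacement rule
#'
#' @param near_cm T2 distance to the moving object (cm) below which an
#'   unstable unit follows the object's move vector; farther units move
#'   against it.
#' @param mag_cm Range (cm) of the opposing / isotropic displacement length.
#' @param jitter_cm SD of isotropic jitter added to every displacement.
#' @return Named list.
#' @export
unstable_rule <- function(near_cm = 12, mag_cm = c(8, 14), jitter_cm = 1) {
  list(near_cm = near_cm, mag_cm = mag_cm, jitter_cm = jitter_cm)
}

#' Generate a complete synthetic OPM session
#'
#' Builds a full session with known ground truth: per-trial trajectories
#' (15-min T1, 5-min T2 and T3, 10-min delays), an object layout, a cohort of
#' Gaussian-tuned units whose across-trial dynamics are sampled from class
#' probabilities, inhomogeneous-Poisson spike trains, and an optional
#' CPP-like perturbation applied to every tuning. All randomness flows
#' through named substreams of `seed`, so changing `n_units` does not perturb
#' the trajectories and the same seed reproduces the dataset exactly.
#'
#' @param n_units Number of units in the cohort.
#' @param probs Class-dynamics probabilities, see [class_probs()].
#' @param effect A [condition_effect()]; `condition_effect("SAL")` leaves
#'   tunings untouched.
#' @param layout An [object_layout()].
#' @param arena An [arena_spec()].
#' @param motion A [motion_params()] list.
#' @param object_bias_gain If > 1, T2/T3 trajectories dwell longer inside
#'   object zones by this factor; 1 (default) disables the bias.
#' @param rule Unstable-displacement rule, see [unstable_rule()].
#' @param seed Master session seed (integer).
#' @param spikes If `FALSE`, skip spike simulation (ground-truth labels and
#'   trajectories only); useful for label-frequency studies.
#' @return Object of class `opm_session`: `manifest` (condition, seed, arena,
#'   trial table, layout), `trajectories` (list T1/T2/T3), `spikes` (list per
#'   unit of numeric spike-time vectors), `ground_truth` (per-unit labels and
#'   per-trial tuning parameters).
#' @export
generate_opm_session <- function(n_units = 50, probs = class_probs(),
                                 effect = condition_effect("SAL"),
                                 layout = object_layout(),
                                 arena = arena_spec(),
                                 motion = motion_params(),
                                 object_bias_gain = 1,
                                 rule = unstable_rule(),
                                 seed = 1, spikes = TRUE) {
  if (n_units < 1) stop("empty cohort: n_units must be >= 1")
  probs <- class_probs(probs$t1_t2, probs$t2_t3)  # re-validate
  ss <- stream_seeds(seed)
  trials <- .trial_table()

  bias <- NULL
  if (object_bias_gain > 1)
    bias <- function(trial) list(layout = layout, trial = trial,
                                 dwell_gain = object_bias_gain)
  traj <- list()
  for (k in seq_len(nrow(trials))) {
    tr <- trials$trial[k]
    ob <- if (!is.null(bias) && tr != "T1") bias(tr) else NULL
    traj[[tr]] <- generate_trajectory(
      duration = trials$end_s[k] - trials$start_s[k], arena = arena,
      motion = motion, object_bias = ob,
      seed = substream_seed(ss["trajectory"], k), t0 = trials$start_s[k])
  }

  # --- unit assignment stream: classes, tunings, dynamics ---
  local_seed(substream_seed(ss["units"], 0L))
  classes <- c("stable", "unstable", "emerging", "vanishing", "inactive")
  c12 <- sample(classes, n_units, replace = TRUE, prob = probs$t1_t2)
  active_t2 <- c12 %in% c("stable", "unstable", "emerging")
  c23 <- character(n_units)
  for (i in seq_len(n_units)) {
    ok <- if (active_t2[i]) c("stable", "unstable", "vanishing")
          else c("emerging", "inactive")
    p <- probs$t2_t3[ok]
    if (sum(p) <= 0) p <- rep(1, length(ok))
    c23[i] <- sample(ok, 1, prob = p / sum(p))
  }

  gt <- vector("list", n_units)
  tunings <- vector("list", n_units)
  for (i in seq_len(n_units)) {
    active_t1 <- c12[i] %in% c("stable", "unstable", "vanishing")
    tun_t1 <- .draw_tuning(active_t1, arena)
    # T1 -> T2
    tun_t2 <- switch(c12[i],
      stable = tun_t1,
      unstable = {
        ctr <- .displace_center(tun_t1$center, rule, layout, "t1_t2", arena)
        tuning_spec(ctr, tun_t1$sigma, tun_t1$peak, tun_t1$baseline, arena = arena)
      },
      emerging = .draw_tuning(TRUE, arena),
      vanishing = .draw_tuning(FALSE, arena),
      inactive = tun_t1)
    # T2 -> T3
    tun_t3 <- switch(c23[i],
      stable = tun_t2,
      unstable = {
        ctr <- .displace_center(tun_t2$center, rule, layout, "t2_t3", arena)
        tuning_spec(ctr, tun_t2$sigma, tun_t2$peak, tun_t2$baseline, arena = arena)
      },
      emerging = .draw_tuning(TRUE, arena),
      vanishing = .draw_tuning(FALSE, arena),
      inactive = tun_t2)
    tun <- list(T1 = tun_t1, T2 = tun_t2, T3 = tun_t3)
    tun <- lapply(tun, apply_condition, effect = effect, arena = arena)
    tunings[[i]] <- tun
    gt[[i]] <- data.frame(
      unit = i, trial = c("T1", "T2", "T3"),
      class_t1_t2 = c12[i], class_t2_t3 = c23[i],
      center_x = vapply(tun, function(s) s$center[1], 0),
      center_y = vapply(tun, function(s) s$center[2], 0),
      sigma = vapply(tun, function(s) s$sigma, 0),
      peak = vapply(tun, function(s) s$peak, 0),
      baseline = vapply(tun, function(s) s$baseline, 0),
      stringsAsFactors = FALSE)
  }
  ground_truth <- do.call(rbind, gt)
  rownames(ground_truth) <- NULL

  spk <- stats::setNames(vector("list", n_units),
                         sprintf("unit_%03d", seq_len(n_units)))
  if (spikes) {
    for (i in seq_len(n_units)) {
      s <- numeric(0)
      for (k in seq_len(nrow(trials))) {
        tr <- trials$trial[k]
        s <- c(s, simulate_spikes(
          tunings[[i]][[tr]], traj[[tr]],
          seed = substream_seed(ss["spikes"], (i - 1L) * 8L + k),
          arena = arena))
      }
      spk[[i]] <- s
    }
  } else {
    spk <- lapply(spk, function(.) numeric(0))
  }

  structure(list(
    manifest = list(condition = effect$condition, seed = seed, arena = arena,
                    trials = trials, layout = layout),
    trajectories = traj,
    spikes = spk,
    ground_truth = ground_truth,
    tunings = tunings),
    class = "opm_session")
}

#' @export
print.opm_session <- function(x, ...) {
  cat(sprintf("<opm_session> condition %s, %d units, seed %s\n",
              x$manifest$condition, length(x$spikes),
              format(x$manifest$seed)))
  print(x$manifest$trials)
  invisible(x)
}
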
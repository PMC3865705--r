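#' Read / write nose-tracking CSV
#'
#' Tracking files are plain CSV with a required `time_s,x_cm,y_cm` header,
#' one row per video frame.
#'
#' @param path File path.
#' @param arena An [arena_spec()] attached to the returned trajectory.
#' @param frame_rate Frames per second; inferred from the timestamps when
#'   `NULL`.
#' @return A `trajectory` data.frame.
#' @export
read_tracking_csv <- function(path, arena = arena_spec(), frame_rate = NULL) {
  df <- utils::read.csv(path)
  need <- c("time_s", "x_cm", "y_cm")
  if (!all(need %in% names(df)))
    stop("tracking CSV must have header time_s,x_cm,y_cm")
  if (is.null(frame_rate))  # timestamps are written at finite precision;
    frame_rate <- round(1 / stats::median(diff(df$time_s)), 3)
  out <- df[, need]
  attr(out, "frame_rate") <- frame_rate
  attr(out, "arena") <- arena
  class(out) <- c("trajectory", "data.frame")
  out
}

#' @rdname read_tracking_csv
#' @param traj A `trajectory` to write.
#' @export
write_tracking_csv <- function(traj, path) {
  utils::write.csv(as.data.frame(traj)[, c("time_s", "x_cm", "y_cm")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Read / write a per-unit spike-time CSV
#'
#' One column `time_s`, one row per spike.
#'
#' @param path File path.
#' @return Sorted numeric vector of spike times, s.
#' @export
read_spikes_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!"time_s" %in% names(df))
    stop("spike CSV must have header time_s")
  sort(df$time_s)
}

#' @rdname read_spikes_csv
#' @param spikes Numeric spike times to write.
#' @export
write_spikes_csv <- function(spikes, path) {
  utils::write.csv(data.frame(time_s = spikes), path, row.names = FALSE)
  invisible(path)
}

#' Write a rate map as a plain-text grid
#'
#' The file holds a commented header (grid spec, occupancy threshold,
#' smoothing flag), then the rate grid (rows = y bins from north to south for
#' readability, columns = x bins west to east, `NA` for invalid pixels), then
#' the validity mask as 0/1 on the same layout.
#'
#' @param map A `rate_map`.
#' @param path File path.
#' @export
write_rate_map_txt <- function(map, path) {
  n <- map$arena$n_bins
  fmt_row <- function(m, i) paste(signif(m[, i], 8), collapse = " ")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# side_length_cm: %g", map$arena$side_length),
    sprintf("# bin_size_cm: %g", map$arena$bin_size),
    sprintf("# min_occupancy_s: %g", map$min_occupancy),
    sprintf("# smoothed: %s", map$smoothed),
    sprintf("# overall_rate_hz: %.8g", map$overall_rate),
    "# rate grid (rows north to south):"), con)
  for (i in rev(seq_len(n))) writeLines(fmt_row(map$rate, i), con)
  writeLines("# validity mask:", con)
  for (i in rev(seq_len(n)))
    writeLines(paste(as.integer(map$mask[, i]), collapse = " "), con)
  invisible(path)
}

#' Read a rate map written by [write_rate_map_txt()]
#' @param path File path.
#' @return A `rate_map` (without dwell information; `dwell` is set to the
#'   mask so occupancy-weighted summaries degrade to unweighted ones).
#' @export
read_rate_map_txt <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  get <- function(key) {
    ln <- grep(paste0("^# ", key, ":"), lines, value = TRUE)
    sub(paste0("^# ", key, ": *"), "", ln)
  }
  arena <- arena_spec(as.numeric(get("side_length_cm")),
                      as.numeric(get("bin_size_cm")))
  n <- arena$n_bins
  body <- setdiff(seq_along(lines), hdr)
  rate_lines <- body[1:n]
  mask_lines <- body[(n + 1):(2 * n)]
  parse_grid <- function(ix) {
    m <- t(unname(vapply(lines[ix], function(s) {
      tok <- strsplit(trimws(s), " +")[[1]]
      tok[tok == "NA"] <- NA_character_
      as.numeric(tok)
    }, numeric(n))))
    # file rows are y bins north->south; transpose back to [ix, iy]
    t(m[rev(seq_len(n)), , drop = FALSE])
  }
  rate <- parse_grid(rate_lines)
  mask <- parse_grid(mask_lines) > 0
  structure(list(rate = rate, mask = mask, dwell = mask * 1,
                 overall_rate = as.numeric(get("overall_rate_hz")),
                 smoothed = as.logical(get("smoothed")), arena = arena,
                 min_occupancy = as.numeric(get("min_occupancy_s"))),
            class = "rate_map")
}

#' Write a session dataset to a directory
#'
#' Writes the manifest (YAML), per-trial tracking CSVs, per-unit spike CSVs
#' and the ground-truth sidecar table, in the same formats the analysis
#' reads.
#'
#' @param session An `opm_session`.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- session$manifest
  lay <- man$layout
  yaml::write_yaml(list(
    condition = man$condition,
    seed = man$seed,
    arena = list(side_length_cm = man$arena$side_length,
                 bin_size_cm = man$arena$bin_size),
    trials = lapply(seq_len(nrow(man$trials)), function(k)
      list(trial = man$trials$trial[k], start_s = man$trials$start_s[k],
           end_s = man$trials$end_s[k])),
    layout = list(sites = lay$objects$site[lay$objects$trial == "T2"],
                  moved_site = lay$moved_site, dest_site = lay$dest_site,
                  base_diameter = lay$objects$base_diameter[1],
                  proximity_cm = (lay$objects$zone_diameter[1] -
                                    lay$objects$base_diameter[1]) / 2)),
    file.path(dir, "manifest.yaml"))
  for (tr in names(session$trajectories))
    write_tracking_csv(session$trajectories[[tr]],
                       file.path(dir, sprintf("tracking_%s.csv", tr)))
  for (u in names(session$spikes))
    write_spikes_csv(session$spikes[[u]],
                     file.path(dir, sprintf("spikes_%s.csv", u)))
  if (!is.null(session$ground_truth))
    utils::write.csv(session$ground_truth,
                     file.path(dir, "ground_truth_synthetic.csv"),
                     row.names = FALSE)
  invisible(dir)
}

#' Read a session dataset from a directory written by [write_session()]
#' @param dir Session directory.
#' @return An `opm_session` (without tuning objects; `ground_truth` is
#'   reloaded when the sidecar file exists).
#' @export
read_session <- function(dir) {
  man <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  arena <- arena_spec(man$arena$side_length_cm, man$arena$bin_size_cm)
  layout <- object_layout(sites = unlist(man$layout$sites),
                          moved_site = man$layout$moved_site,
                          dest_site = man$layout$dest_site,
                          base_diameter = man$layout$base_diameter,
                          proximity_cm = man$layout$proximity_cm,
                          arena = arena)
  trials <- do.call(rbind, lapply(man$trials, function(t)
    data.frame(trial = t$trial, start_s = t$start_s, end_s = t$end_s,
               stringsAsFactors = FALSE)))
  traj <- list()
  for (tr in trials$trial)
    traj[[tr]] <- read_tracking_csv(
      file.path(dir, sprintf("tracking_%s.csv", tr)), arena)
  spike_files <- sort(list.files(dir, "^spikes_unit_.*\\.csv$"))
  spikes <- lapply(spike_files, function(f)
    read_spikes_csv(file.path(dir, f)))
  names(spikes) <- sub("^spikes_(unit_[0-9]+)\\.csv$", "\\1", spike_files)
  gt_path <- file.path(dir, "ground_truth_synthetic.csv")
  gt <- if (file.exists(gt_path)) utils::read.csv(gt_path) else NULL
  structure(list(
    manifest = list(condition = man$condition, seed = man$seed,
                    arena = arena, trials = trials, layout = layout),
    trajectories = traj, spikes = spikes, ground_truth = gt),
    class = "opm_session")
}
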
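#' Normality-gated two-group comparison
#'
#' The comparison scheme applied to every grouped metric: each sample is
#' tested for normality with the Shapiro-Wilk test at `alpha`; if both pass,
#' a two-sample Student's t-test is used and the groups are described as
#' mean +/- s.e.m.; otherwise the configured nonparametric test
#' (two-sample Kolmogorov-Smirnov or Mann-Whitney U) is used and the groups
#' are described as median +/- IQR.
#'
#' @param a,b Numeric samples (n >= 3 each).
#' @param alpha Normality-gate level (default 0.05).
#' @param nonparam_test "ks" or "mann-whitney".
#' @param labels Character(2) group labels.
#' @param metric Name of the compared metric (for reporting).
#' @return Object of class `group_comparison`: metric, labels, n, the
#'   Shapiro-Wilk p-values, `test` used, `statistic`, `p`, and a
#'   `descriptives` data.frame matching the test family.
#' @export
compare_groups <- function(a, b, alpha = 0.05,
                           nonparam_test = c("ks", "mann-whitney"),
                           labels = c("a", "b"), metric = "metric") {
  nonparam_test <- match.arg(nonparam_test)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 3 || length(b) < 3)
    stop("need at least 3 observations per group")
  sw_a <- stats::shapiro.test(a)$p.value
  sw_b <- stats::shapiro.test(b)$p.value
  normal <- sw_a > alpha && sw_b > alpha
  if (normal) {
    ht <- stats::t.test(a, b, var.equal = TRUE)
    test <- "t"
    desc <- data.frame(
      group = labels,
      n = c(length(a), length(b)),
      center = c(mean(a), mean(b)),
      spread = c(stats::sd(a) / sqrt(length(a)),
                 stats::sd(b) / sqrt(length(b))),
      family = "mean_sem", stringsAsFactors = FALSE)
  } else {
    ht <- if (nonparam_test == "ks") stats::ks.test(a, b)
          else stats::wilcox.test(a, b)
    test <- if (nonparam_test == "ks") "ks" else "mann-whitney"
    desc <- data.frame(
      group = labels,
      n = c(length(a), length(b)),
      center = c(stats::median(a), stats::median(b)),
      spread = c(stats::IQR(a), stats::IQR(b)),
      family = "median_iqr", stringsAsFactors = FALSE)
  }
  structure(list(metric = metric, labels = labels,
                 n = c(length(a), length(b)),
                 shapiro_p = c(sw_a, sw_b), normal = normal,
                 test = test, statistic = unname(ht$statistic),
                 p = ht$p.value, descriptives = desc),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s: %s test, statistic = %.4g, P = %.4g\n",
              x$metric, x$test, x$statistic, x$p))
  print(x$descriptives)
  invisible(x)
}

#' Chi-square test on class frequencies between groups
#'
#' Pearson chi-square (without continuity correction, i.e. the textbook
#' `sum (O - E)^2 / E`) on the group x class contingency table of unit
#' counts.
#'
#' @param counts_a,counts_b Named integer vectors of per-class counts over
#'   the same class set.
#' @return `group_comparison`-style list with `statistic` (X^2), `df`, `p`.
#' @export
class_frequency_test <- function(counts_a, counts_b) {
  if (!identical(sort(names(counts_a)), sort(names(counts_b))))
    stop("class sets differ between groups")
  counts_b <- counts_b[names(counts_a)]
  tab <- rbind(a = counts_a, b = counts_b)
  exp_counts <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(exp_counts == 0))
    stop("zero expected count; merge sparse classes before testing")
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  structure(list(metric = "class_frequencies", test = "chi-square",
                 statistic = unname(ht$statistic),
                 df = unname(ht$parameter), p = ht$p.value, table = tab),
            class = "group_comparison")
}

#' Analysis parameters
#'
#' @param min_occupancy_s Pixel occupancy exclusion threshold, s.
#' @param kernel_radius_bins,kernel_sigma_bins Smoothing kernel geometry.
#' @param active_threshold_hz Active/inactive peak-rate boundary, Hz.
#' @param stability_boundary_cm Stable/unstable COM-shift boundary, cm.
#' @param speed_threshold Movement threshold, cm/s.
#' @param nonparam_test Nonparametric branch of the gate ("ks" or
#'   "mann-whitney").
#' @return Named list of analysis parameters.
#' @export
analysis_params <- function(min_occupancy_s = 0.1, kernel_radius_bins = 2,
                            kernel_sigma_bins = 1, active_threshold_hz = 3,
                            stability_boundary_cm = 7, speed_threshold = 2,
                            nonparam_test = "ks") {
  list(min_occupancy_s = min_occupancy_s,
       kernel_radius_bins = kernel_radius_bins,
       kernel_sigma_bins = kernel_sigma_bins,
       active_threshold_hz = active_threshold_hz,
       stability_boundary_cm = stability_boundary_cm,
       speed_threshold = speed_threshold,
       nonparam_test = nonparam_test)
}

#' Analyze a full OPM session
#'
#' Runs the complete per-unit pipeline on a session: rate maps per trial
#' (occupancy-excluded, smoothed), rate summaries, spatial information,
#' place fields and COMs; per-transition classification, COM shift,
#' similarity, object proximity and vector index; and the behavioral
#' summary.
#'
#' @param session An `opm_session` (from [generate_opm_session()] or
#'   [read_session()]).
#' @param params An [analysis_params()] list.
#' @return List of class `opm_report`: `unit_trial` (per unit x trial
#'   metrics), `transitions` (per unit x transition metrics), `cohort`
#'   (class-frequency table), `behavior`, `params`, `condition`.
#' @export
analyze_session <- function(session, params = analysis_params()) {
  arena <- session$manifest$arena
  layout <- session$manifest$layout
  trials <- session$manifest$trials$trial
  kernel <- gaussian_kernel(params$kernel_radius_bins,
                            params$kernel_sigma_bins)
  units <- names(session$spikes)
  if (length(units) == 0L) stop("empty cohort: session has no units")
  cond <- session$manifest$condition

  maps <- list()
  ut <- list()
  for (tr in trials) {
    traj <- session$trajectories[[tr]]
    span <- range(traj$time_s)
    occ <- bin_occupancy(traj, arena)
    for (u in units) {
      s <- session$spikes[[u]]
      s <- s[s >= span[1] & s <= span[2]]
      cnt <- bin_spikes(s, traj, arena)
      raw <- compute_rate_map(occ, cnt, params$min_occupancy_s)
      sm <- smooth_rate_map(raw, kernel)
      maps[[tr]][[u]] <- sm
      rs <- summarize_rates(sm)
      si <- if (rs$peak_hz > 0) spatial_information(sm)$bits_per_spike
            else NA_real_
      fld <- if (rs$peak_hz > 0) detect_place_field(sm) else NULL
      com <- if (rs$peak_hz > 0) center_of_mass(sm, "auto", field = fld)
             else NULL
      ut[[length(ut) + 1L]] <- data.frame(
        unit_id = u, trial = tr, condition = cond,
        n_spikes = length(s), peak_hz = rs$peak_hz, mean_hz = rs$mean_hz,
        si_bits_per_spike = si,
        field_size_cm2 = if (is.null(fld)) NA_real_ else fld$size_cm2,
        com_x = if (is.null(com)) NA_real_ else com[["x"]],
        com_y = if (is.null(com)) NA_real_ else com[["y"]],
        com_scope = if (is.null(com)) NA_character_ else attr(com, "scope"),
        stringsAsFactors = FALSE)
    }
  }
  unit_trial <- do.call(rbind, ut)
  rownames(unit_trial) <- NULL

  qc <- quadrant_centers(arena)
  moved_t2 <- qc[layout$moved_site, ]
  transitions <- list()
  for (k in 1:2) {
    from <- trials[k]; to <- trials[k + 1]
    trname <- paste0(from, "_", to)
    for (u in units) {
      pk_a <- unit_trial$peak_hz[unit_trial$unit_id == u &
                                   unit_trial$trial == from]
      pk_b <- unit_trial$peak_hz[unit_trial$unit_id == u &
                                   unit_trial$trial == to]
      cls <- classify_transition(pk_a, pk_b, params$active_threshold_hz)
      shift <- sim <- vi <- t2d <- NA_real_
      stab <- NA_character_
      if (cls == "active") {
        cs <- com_shift(maps[[from]][[u]], maps[[to]][[u]])
        shift <- cs$distance_cm
        stab <- split_stability(shift, params$stability_boundary_cm)
        if (trname == "T2_T3") {
          t2d <- sqrt(sum((cs$com_a - moved_t2)^2))
          vi <- vector_index(cs$com_a, cs$com_b, layout$move_vector)
        }
      }
      if (cls %in% c("active", "emerging", "vanishing"))
        sim <- as.numeric(similarity_score(maps[[from]][[u]], maps[[to]][[u]]))
      transitions[[length(transitions) + 1L]] <- data.frame(
        unit_id = u, transition = trname, condition = cond, class = cls,
        stability = stab, com_shift_cm = shift, similarity_r = sim,
        t2_distance_cm = t2d, vector_index_cm = vi,
        stringsAsFactors = FALSE)
    }
  }
  transitions <- do.call(rbind, transitions)
  rownames(transitions) <- NULL

  labels <- data.frame(unit = transitions$unit_id, group = cond,
                       transition = transitions$transition,
                       class = transitions$class, stringsAsFactors = FALSE)
  structure(list(unit_trial = unit_trial, transitions = transitions,
                 cohort = cohort_table(labels),
                 behavior = score_behavior(
                   session, speed_threshold = params$speed_threshold),
                 params = params, condition = cond),
            class = "opm_report")
}

#' @export
print.opm_report <- function(x, ...) {
  cat(sprintf("<opm_report> condition %s, %d units x %d trials\n",
              x$condition, length(unique(x$unit_trial$unit_id)),
              length(unique(x$unit_trial$trial))))
  print(x$cohort)
  invisible(x)
}

#' Run the full pipeline from a config
#'
#' Generates (or loads) one session per condition, analyzes each, compares
#' metric distributions and class frequencies between conditions when both a
#' SAL and a CPP session are present, and writes all result tables plus a
#' parameter/provenance log to `out_dir`. Re-running with the same config and
#' seed writes byte-identical files.
#'
#' @param config Either a named list or the path of a YAML config file.
#'   Recognized keys: `seed`; `simulate` (list: `n_units`, `conditions`);
#'   `sessions` (list of session directories, alternative to `simulate`);
#'   plus any [analysis_params()] name.
#' @param out_dir Output directory (created if needed); `NULL` skips writing.
#' @return List of class `opm_pipeline_result`: `reports` (one `opm_report`
#'   per condition), `group_stats` (data.frame, when two conditions are
#'   present), `files` (written paths with md5 hashes).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  pnames <- names(formals(analysis_params))
  params <- do.call(analysis_params, config[intersect(names(config), pnames)])
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)

  sessions <- list()
  if (!is.null(config$simulate)) {
    sim <- config$simulate
    if (is.null(sim$n_units) || sim$n_units < 1)
      stop("empty cohort: simulate$n_units must be >= 1")
    conds <- if (is.null(sim$conditions)) "SAL" else sim$conditions
    for (i in seq_along(conds)) {
      sessions[[conds[i]]] <- generate_opm_session(
        n_units = sim$n_units,
        effect = condition_effect(conds[i]),
        seed = substream_seed(seed, i))
    }
  } else if (!is.null(config$sessions)) {
    for (p in config$sessions) {
      s <- read_session(p)
      sessions[[s$manifest$condition]] <- s
    }
  } else stop("config must name either a simulate block or session paths")

  reports <- lapply(sessions, analyze_session, params = params)

  group_stats <- NULL
  n_tests <- 0L
  if (all(c("SAL", "CPP") %in% names(reports))) {
    gs <- list()
    for (metric in c("peak_hz", "mean_hz", "si_bits_per_spike",
                     "field_size_cm2")) {
      a <- reports$SAL$unit_trial[[metric]][reports$SAL$unit_trial$trial == "T1"]
      b <- reports$CPP$unit_trial[[metric]][reports$CPP$unit_trial$trial == "T1"]
      cmp <- try(compare_groups(a, b, nonparam_test = params$nonparam_test,
                                labels = c("SAL", "CPP"), metric = metric),
                 silent = TRUE)
      if (!inherits(cmp, "try-error"))
        gs[[metric]] <- data.frame(metric = metric, test = cmp$test,
                                   statistic = cmp$statistic, p = cmp$p,
                                   n_sal = cmp$n[1], n_cpp = cmp$n[2],
                                   stringsAsFactors = FALSE)
    }
    for (trn in c("T1_T2", "T2_T3")) {
      ca <- table(reports$SAL$transitions$class[
        reports$SAL$transitions$transition == trn])
      cb <- table(reports$CPP$transitions$class[
        reports$CPP$transitions$transition == trn])
      classes <- union(names(ca), names(cb))
      va <- stats::setNames(as.integer(ca[classes]), classes)
      vb <- stats::setNames(as.integer(cb[classes]), classes)
      va[is.na(va)] <- 0L; vb[is.na(vb)] <- 0L
      cmp <- try(class_frequency_test(va, vb), silent = TRUE)
      if (!inherits(cmp, "try-error"))
        gs[[paste0("classes_", trn)]] <- data.frame(
          metric = paste0("class_frequencies_", trn), test = "chi-square",
          statistic = cmp$statistic, p = cmp$p,
          n_sal = sum(va), n_cpp = sum(vb), stringsAsFactors = FALSE)
    }
    group_stats <- do.call(rbind, gs)
    rownames(group_stats) <- NULL
    n_tests <- nrow(group_stats)
  }

  files <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(df, name) {
      p <- file.path(out_dir, name)
      utils::write.csv(df, p, row.names = FALSE)
      p
    }
    for (cond in names(reports)) {
      rep <- reports[[cond]]
      files <- c(files,
                 wr(rep$unit_trial, sprintf("unit_trial_metrics_%s.csv", cond)),
                 wr(rep$transitions, sprintf("transitions_%s.csv", cond)),
                 wr(rep$cohort, sprintf("cohort_summary_%s.csv", cond)),
                 wr(rep$behavior$visits, sprintf("behavior_visits_%s.csv", cond)))
      bsum <- data.frame(
        condition = cond,
        exploration_ratio_quotient = rep$behavior$exploration_ratio,
        exploration_ratio_di = rep$behavior$exploration_di,
        opm_ratio = rep$behavior$opm_ratio,
        pct_moving_T1 = rep$behavior$pct_moving[["T1"]],
        pct_moving_T2 = rep$behavior$pct_moving[["T2"]],
        pct_moving_T3 = rep$behavior$pct_moving[["T3"]])
      files <- c(files, wr(bsum, sprintf("behavior_summary_%s.csv", cond)))
    }
    if (!is.null(group_stats))
      files <- c(files, wr(group_stats, "group_stats.csv"))
    log_path <- file.path(out_dir, "log.txt")
    hashes <- tools::md5sum(files)
    log_lines <- c(
      "opmplace pipeline log",
      sprintf("seed: %d", seed),
      sprintf("conditions: %s", paste(names(reports), collapse = ", ")),
      sprintf("n_tests_run: %d (no multiple-testing correction applied)",
              n_tests),
      "parameters:",
      sprintf("  %s: %s", names(params), unlist(params)),
      "output md5:",
      sprintf("  %s  %s", unname(hashes), basename(names(hashes))))
    writeLines(log_lines, log_path)
    files <- c(files, log_path)
  }

  structure(list(reports = reports, group_stats = group_stats,
                 params = params, seed = seed, files = files),
            class = "opm_pipeline_result")
}
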
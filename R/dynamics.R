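#' Classify a unit as active or inactive
#'
#' Units with peak firing rate at or above the activity boundary (3 Hz) are
#' active; below it, inactive.
#'
#' @param peak_hz Peak firing rate, Hz (or a `rate_summary`).
#' @param threshold_hz Activity boundary, Hz (default 3).
#' @return "active" or "inactive".
#' @export
classify_activity <- function(peak_hz, threshold_hz = 3) {
  if (inherits(peak_hz, "rate_summary")) peak_hz <- peak_hz$peak_hz
  if (is.na(peak_hz) || peak_hz < 0) stop("peak rate must be a nonnegative number")
  if (peak_hz >= threshold_hz) "active" else "inactive"
}

#' Classify a unit across a trial transition
#'
#' The four classes partition every unit at each transition: active in both
#' trials -> "active"; inactive then active -> "emerging"; active then
#' inactive -> "vanishing"; inactive in both -> "inactive".
#'
#' @param peak_before,peak_after Peak rates (Hz, or `rate_summary`) in the
#'   two consecutive trials.
#' @param threshold_hz Activity boundary, Hz.
#' @return One of "active", "emerging", "vanishing", "inactive".
#' @export
classify_transition <- function(peak_before, peak_after, threshold_hz = 3) {
  a <- classify_activity(peak_before, threshold_hz) == "active"
  b <- classify_activity(peak_after, threshold_hz) == "active"
  if (a && b) "active" else if (!a && b) "emerging"
  else if (a && !b) "vanishing" else "inactive"
}

#' Split active units into stable and unstable by COM shift
#'
#' @param shift_cm Between-trial COM shift, cm (>= 0).
#' @param boundary_cm Split boundary, cm (default 7): shifts below it are
#'   stable, at or above it unstable.
#' @return "stable" or "unstable".
#' @export
split_stability <- function(shift_cm, boundary_cm = 7) {
  if (is.na(shift_cm) || shift_cm < 0) stop("COM shift must be nonnegative")
  if (shift_cm < boundary_cm) "stable" else "unstable"
}

#' Object-vector index of a place field
#'
#' Magnitude of the difference between the object's displacement vector and
#' the field's COM displacement vector between the sample and choice trials:
#' zero exactly when the field moves along the same vector as the object, and
#' `|move| + |COM displacement|` when it moves exactly opposite.
#'
#' @param com_t2,com_t3 Field COMs, numeric (x, y) in cm.
#' @param move_vector Object displacement (dx, dy), cm.
#' @return Vector index, cm (>= 0).
#' @export
vector_index <- function(com_t2, com_t3, move_vector) {
  disp <- c(com_t3[[1]] - com_t2[[1]], com_t3[[2]] - com_t2[[2]])
  sqrt(sum((move_vector - disp)^2))
}

#' Tabulate unit classes per group
#'
#' @param labels data.frame with at least columns `unit`, `class` and
#'   optionally `group` (condition label) and `transition`.
#' @return data.frame with group, (transition,) class, count and percent;
#'   percentages sum to 100 within each group x transition.
#' @export
cohort_table <- function(labels) {
  if (any(is.na(labels$class))) stop("unlabeled unit in cohort")
  if (is.null(labels$group)) labels$group <- "all"
  if (is.null(labels$transition)) labels$transition <- "all"
  classes <- c("active", "emerging", "vanishing", "inactive")
  out <- expand.grid(group = unique(labels$group),
                     transition = unique(labels$transition),
                     class = classes, stringsAsFactors = FALSE)
  out$count <- mapply(function(g, tr, cl)
    sum(labels$group == g & labels$transition == tr & labels$class == cl),
    out$group, out$transition, out$class)
  tot <- stats::ave(out$count, out$group, out$transition, FUN = sum)
  out$percent <- ifelse(tot > 0, 100 * out$count / tot, NA_real_)
  out[order(out$group, out$transition, match(out$class, classes)), ,
      drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

#' Object-vector correlation analysis
#'
#' For active units on the choice-trial transition, correlates (a) COM shift
#' with T2 distance to the moving object, (b) vector index with COM shift,
#' and (c) vector index with T2 distance, the last computed separately for
#' the stable and unstable subsets. A positive vector-index/T2-distance
#' correlation in unstable units is the signature of fields near the moving
#' object following it while far fields move against it.
#'
#' @param records data.frame with columns `com_shift_cm`, `t2_distance_cm`,
#'   `vector_index_cm`, `stability` ("stable"/"unstable").
#' @param min_n Minimum records per correlation (default 3).
#' @return data.frame: `subset`, `pair`, `r`, `n`, `p` (`r` is `NA` when
#'   `n < min_n`).
#' @export
object_vector_analysis <- function(records, min_n = 3) {
  one <- function(x, y, subset, pair) {
    ok <- stats::complete.cases(x, y)
    x <- x[ok]; y <- y[ok]
    if (length(x) < min_n || stats::sd(x) == 0 || stats::sd(y) == 0)
      return(data.frame(subset = subset, pair = pair, r = NA_real_,
                        n = length(x), p = NA_real_))
    ct <- stats::cor.test(x, y)
    data.frame(subset = subset, pair = pair, r = unname(ct$estimate),
               n = length(x), p = ct$p.value, stringsAsFactors = FALSE)
  }
  res <- list(
    one(records$com_shift_cm, records$t2_distance_cm, "all",
        "com_shift~t2_distance"),
    one(records$vector_index_cm, records$com_shift_cm, "all",
        "vector_index~com_shift"))
  for (s in c("stable", "unstable")) {
    rr <- records[records$stability %in% s, , drop = FALSE]
    res <- c(res, list(one(rr$vector_index_cm, rr$t2_distance_cm, s,
                           "vector_index~t2_distance")))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
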
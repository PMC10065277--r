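# Behavioural measures: per-condition preferred distances from the proximity
# trace, active/passive pooling, and baseline-standardised HRV.

#' Detect the eight episode minima of a session trace
#'
#' Segments the resampled trace into episodes at crossings of a separation
#' threshold (default 300 cm -- between plausible stop distances and the
#' 500 cm reset position) and returns, per segment, the earliest sample
#' attaining the segment minimum. Condition keys are attached from the
#' session's recorded episode order.
#'
#' @param trace a 1 Hz `proximity_trace` containing the task segment.
#' @param episode_order 8-row data frame of condition keys in presentation
#'   order (see [condition_keys()]).
#' @param n_expected expected number of episodes (8 for the full paradigm).
#' @param threshold_cm separation threshold in cm.
#' @return A `trigger_set` with the detected minimum times and their keys.
#' @export
detect_episode_minima <- function(trace, episode_order, n_expected = 8,
                                  threshold_cm = 300) {
  stopifnot(inherits(trace, "proximity_trace"))
  if (!identical(trace_resolution(trace), "1hz")) {
    stop_user("detect_episode_minima expects a resampled (1 Hz) trace")
  }
  below <- trace$distance_cm < threshold_cm
  r <- rle(below)
  seg_id <- which(r$values)
  if (length(seg_id) != n_expected) {
    stop_user("found %d episodes below %.0f cm, expected %d",
              length(seg_id), threshold_cm, n_expected)
  }
  validate_episode_order(episode_order)
  starts <- cumsum(c(1L, r$lengths))[seg_id]
  ends <- starts + r$lengths[seg_id] - 1L
  t_min <- vapply(seq_along(starts), function(j) {
    seg <- starts[j]:ends[j]
    trace$t_ms[seg[which.min(trace$distance_cm[seg])]] / 1000  # earliest on ties
  }, numeric(1))
  new_trigger_set(t_min, episode_order)
}

#' Read per-condition preferred distances at the trigger times
#'
#' @param trace a 1 Hz `proximity_trace`.
#' @param triggers an aligned `trigger_set`.
#' @param participant optional participant id attached to every row.
#' @return A `distance_table` data frame: one row per condition with columns
#'   `eye_contact`, `attribution`, `role`, `distance_cm` (and `participant`).
#' @export
extract_condition_distances <- function(trace, triggers, participant = NULL) {
  stopifnot(inherits(trace, "proximity_trace"), inherits(triggers, "trigger_set"))
  if (!identical(trace_resolution(trace), "1hz")) {
    stop_user("extract_condition_distances expects a resampled (1 Hz) trace")
  }
  t_s <- trace$t_ms / 1000
  d <- vapply(triggers$t_s, function(t) {
    if (t < t_s[1] || t > t_s[length(t_s)] + 1) {
      stop_user("trigger at %.1f s lies outside the trace span (%.1f-%.1f s)",
                t, t_s[1], t_s[length(t_s)])
    }
    trace$distance_cm[max(which(t_s <= t))]  # value of the second bin hit
  }, numeric(1))
  out <- data.frame(eye_contact = triggers$eye_contact,
                    attribution = triggers$attribution,
                    role = triggers$role, distance_cm = d,
                    stringsAsFactors = FALSE)
  if (!is.null(participant)) out <- cbind(participant = participant, out)
  structure(out, class = c("distance_table", "data.frame"))
}

#' Pool active and passive episodes of each condition pair
#'
#' The paradigm's eight raw cells collapse to four: for every eye-contact by
#' attribution pair the pooled preferred distance is the arithmetic mean of
#' its active and passive cells. A missing raw cell leaves the pooled cell
#' `NA` with a warning.
#'
#' @param table a raw `distance_table` (8 cells per participant).
#' @return A pooled `distance_table` with `role = "pooled"`.
#' @export
pool_active_passive <- function(table) {
  stopifnot(inherits(table, "distance_table"))
  has_part <- "participant" %in% names(table)
  by <- list(eye_contact = table$eye_contact, attribution = table$attribution)
  if (has_part) by <- c(list(participant = table$participant), by)
  agg <- aggregate(table["distance_cm"], by = by, FUN = function(v) {
    if (length(v) != 2L || anyNA(v)) NA_real_ else mean(v)
  })
  if (anyNA(agg$distance_cm)) {
    warning(sum(is.na(agg$distance_cm)),
            " pooled cell(s) missing an active or passive raw cell; set to NA")
  }
  agg$role <- "pooled"
  cols <- c(if (has_part) "participant", "eye_contact", "attribution", "role",
            "distance_cm")
  structure(agg[cols], class = c("distance_table", "data.frame"))
}

#' Standardise task HRV to the person's baseline
#'
#' Because baseline HRV differs between groups, condition-level HRV is
#' expressed relative to the same person's baseline as the dimensionless
#' ratio `rmssd_condition / rmssd_baseline`. An invalid or zero baseline
#' propagates invalidity to every condition (logged via a warning).
#'
#' @param task_hrv data frame of `hrv_measure` rows (one per condition).
#' @param baseline_hrv a single `hrv_measure` row for the baseline window.
#' @return `task_hrv` with an added `hrv_std` column; `valid` is downgraded
#'   where standardisation is impossible.
#' @export
standardize_hrv <- function(task_hrv, baseline_hrv) {
  stopifnot(is.data.frame(task_hrv), is.data.frame(baseline_hrv),
            nrow(baseline_hrv) == 1L)
  bad_base <- !isTRUE(baseline_hrv$valid) || is.na(baseline_hrv$rmssd) ||
    baseline_hrv$rmssd <= 0
  out <- task_hrv
  if (bad_base) {
    warning("baseline HRV invalid or zero; standardised values are invalid")
    out$hrv_std <- NA_real_
    out$valid <- FALSE
  } else {
    out$hrv_std <- ifelse(out$valid, out$rmssd / baseline_hrv$rmssd, NA_real_)
  }
  out
}
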
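# Cleaning and synchronization: median-per-second resampling, RR artifact
# replacement, missing-data policy, trigger alignment.

#' Construct a cleaning report
#'
#' Audit trail emitted by every cleaning step: how many beats each rule
#' replaced, the replacement value, and which participants were dropped (with
#' reasons).
#'
#' @param n_replaced_threshold beats replaced by the >= 1200 ms rule.
#' @param n_replaced_zscore beats replaced by the |Z| > 2 rule only.
#' @param replacement_value_ms the median used as replacement (NA if unused).
#' @param participants_dropped named character vector: participant -> reason.
#' @param notes free-form log lines.
#' @return Object of class `cleaning_report`.
#' @export
new_cleaning_report <- function(n_replaced_threshold = 0L,
                                n_replaced_zscore = 0L,
                                replacement_value_ms = NA_real_,
                                participants_dropped = character(0),
                                notes = character(0)) {
  stopifnot(n_replaced_threshold >= 0, n_replaced_zscore >= 0)
  structure(list(n_replaced_threshold = as.integer(n_replaced_threshold),
                 n_replaced_zscore = as.integer(n_replaced_zscore),
                 replacement_value_ms = replacement_value_ms,
                 participants_dropped = participants_dropped,
                 notes = notes),
            class = "cleaning_report")
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat("<cleaning_report> replaced ", x$n_replaced_threshold, " (>=1200 ms) + ",
      x$n_replaced_zscore, " (|Z|>2) beats", sep = "")
  if (!is.na(x$replacement_value_ms)) {
    cat(sprintf(" with median %.1f ms", x$replacement_value_ms))
  }
  cat("\n")
  if (length(x$participants_dropped)) {
    cat("  dropped:", paste(names(x$participants_dropped),
                            x$participants_dropped, sep = ": ",
                            collapse = "; "), "\n")
  }
  for (n in x$notes) cat("  note:", n, "\n")
  invisible(x)
}

#' Resample a proximity trace to 1 Hz by per-second medians
#'
#' Samples are binned into half-open second bins `[k, k+1)` anchored at the
#' trace start; each bin's value is the median of its samples (even counts:
#' mean of the two middle values, R's default). Empty interior bins are
#' linearly interpolated from the nearest non-empty neighbours and flagged in
#' the `interpolated` column; empty edge bins carry the nearest value.
#'
#' @param trace a raw-resolution `proximity_trace`.
#' @return A 1 Hz `proximity_trace` of length `ceil(duration)` seconds, with
#'   `t_ms` at bin starts. An empty trace is returned unchanged.
#' @export
resample_proximity <- function(trace) {
  stopifnot(inherits(trace, "proximity_trace"))
  if (!nrow(trace)) {
    return(new_proximity_trace(numeric(0), numeric(0), resolution = "1hz"))
  }
  t0 <- trace$t_ms[1]
  bin <- floor((trace$t_ms - t0) / 1000)
  n_bins <- max(bin) + 1L
  med <- rep(NA_real_, n_bins)
  agg <- tapply(trace$distance_cm, bin, stats::median)
  med[as.integer(names(agg)) + 1L] <- agg
  filled <- is.na(med)
  if (any(filled)) {
    known <- which(!filled)
    med <- stats::approx(known, med[known], xout = seq_len(n_bins), rule = 2)$y
  }
  new_proximity_trace(t0 + (seq_len(n_bins) - 1L) * 1000, med,
                      resolution = "1hz", interpolated = filled)
}

#' Replace artifactual RR intervals by the recording median
#'
#' Single-pass rule on the raw (pre-replacement) series: a beat is flagged if
#' its interval is 1200 ms or above, or if its absolute Z score exceeds 2
#' (mean, sd and median are all computed on the raw series; the sample sd is
#' used). Every flagged beat is replaced by the raw median; timestamps are
#' left untouched. A beat matching both rules is counted once, under the
#' threshold rule. If the raw sd is zero the Z rule is inert (logged).
#'
#' @param stream a `timestamped_rr` (see [reconstruct_timestamps()]).
#' @return A list with elements `stream` (corrected `timestamped_rr`) and
#'   `report` (a [new_cleaning_report()]).
#' @examples
#' s <- new_rr_series(c(800, 805, 1300, 810), Sys.time())
#' correct_artifacts(reconstruct_timestamps(s))$stream$rr_ms
#' @export
correct_artifacts <- function(stream) {
  stopifnot(inherits(stream, "timestamped_rr"))
  if (!nrow(stream)) stop_user("cannot clean an empty RR stream")
  rr <- stream$rr_ms
  mu <- mean(rr)
  sigma <- stats::sd(rr)
  med <- stats::median(rr)
  notes <- character(0)
  flag_thr <- rr >= 1200
  if (is.na(sigma) || sigma == 0) {
    flag_z <- rep(FALSE, length(rr))
    notes <- "raw sd is 0; Z-score rule skipped"
  } else {
    flag_z <- abs(rr - mu) / sigma > 2 & !flag_thr
  }
  out <- stream
  out$rr_ms[flag_thr | flag_z] <- med
  list(stream = out,
       report = new_cleaning_report(
         n_replaced_threshold = sum(flag_thr),
         n_replaced_zscore = sum(flag_z),
         replacement_value_ms = if (any(flag_thr | flag_z)) med else NA_real_,
         notes = notes))
}

#' Listwise missing-data policy for HRV analyses
#'
#' Participants lacking a complete HRV record for any required window (no RR
#' stream, too short a recording, or fewer than 2 beats in the baseline, task
#' or any pre-trigger window) are excluded from HRV analyses but retained for
#' distance-only analyses. Exclusions are logged with reasons.
#'
#' @param cohort a `prox_cohort` (sessions may have `rr = NULL`).
#' @param baseline_window numeric `c(start, end)` seconds of the baseline HRV
#'   window on the session clock.
#' @param task_offset numeric `c(start, end)` seconds of the task window
#'   relative to task start.
#' @param pre_trigger_span_s length of the ultra-short pre-trigger window.
#' @return A list with `hrv_ids` (participants usable for HRV), `distance_ids`
#'   (all participants) and `report` (a [new_cleaning_report()]).
#' @export
drop_incomplete <- function(cohort, baseline_window = c(0, 60),
                            task_offset = c(60, 120), pre_trigger_span_s = 10) {
  stopifnot(inherits(cohort, "prox_cohort"))
  dropped <- character(0)
  ids <- names(cohort$sessions)
  ok <- logical(length(ids))
  for (i in seq_along(ids)) {
    sess <- cohort$sessions[[i]]
    reason <- NULL
    if (is.null(sess$rr)) {
      reason <- "no RR record"
    } else {
      stream <- reconstruct_timestamps(sess$rr)
      # always derived from the trace so simulated and ingested cohorts agree
      task_start <- detect_task_start(resample_proximity(sess$trace))
      windows <- rbind(baseline_window, task_start + task_offset,
                       cbind(sess$triggers$t_s - pre_trigger_span_s,
                             sess$triggers$t_s))
      for (w in seq_len(nrow(windows))) {
        m <- window_rmssd(stream, windows[w, 1], windows[w, 2])
        if (!m$valid) {
          reason <- sprintf("incomplete HRV window (%.0f-%.0f s)",
                            windows[w, 1], windows[w, 2])
          break
        }
      }
    }
    ok[i] <- is.null(reason)
    if (!is.null(reason)) dropped[ids[i]] <- reason
  }
  list(hrv_ids = ids[ok], distance_ids = ids,
       report = new_cleaning_report(participants_dropped = dropped))
}

#' First time the pair leaves the 500 cm start position
#' @param trace a `proximity_trace` (raw or resampled).
#' @param threshold_cm descent threshold; default 490 cm (one noise width
#'   below the start).
#' @return Time in seconds.
#' @export
detect_task_start <- function(trace, threshold_cm = 490) {
  idx <- which(trace$distance_cm < threshold_cm)[1]
  if (is.na(idx)) stop_user("no task segment found: trace never drops below %.0f cm",
                            threshold_cm)
  trace$t_ms[idx] / 1000
}

# Local minima of a 1 Hz trace, plateau runs represented by their first sample.
local_minima_idx <- function(v) {
  r <- rle(v)
  k <- length(r$values)
  if (k == 1L) return(1L)
  first_idx <- cumsum(c(1L, r$lengths[-k]))
  left <- c(Inf, r$values[-k])
  right <- c(r$values[-1], Inf)
  first_idx[r$values < left & r$values < right]
}

#' Snap triggers to nearby local minima of the distance trace
#'
#' Each trigger is moved to the closest local minimum of the resampled trace
#' within `+/- radius_s` seconds (ties resolved towards the earlier minimum);
#' triggers with no minimum in range are left in place with a warning. A
#' per-trigger override table is applied last. The result must be strictly
#' increasing.
#'
#' @param triggers a `trigger_set`.
#' @param trace a 1 Hz `proximity_trace`.
#' @param overrides optional data frame `trigger_index, t_s` of manual
#'   adjustments (the programmatic stand-in for on-screen trigger editing).
#' @param radius_s snap radius in seconds.
#' @return The adjusted `trigger_set`.
#' @export
align_triggers <- function(triggers, trace, overrides = NULL, radius_s = 5) {
  stopifnot(inherits(triggers, "trigger_set"), inherits(trace, "proximity_trace"))
  if (!identical(trace_resolution(trace), "1hz")) {
    stop_user("align_triggers expects a resampled (1 Hz) trace")
  }
  mins_t <- trace$t_ms[local_minima_idx(trace$distance_cm)] / 1000
  t_new <- vapply(triggers$t_s, function(t) {
    cand <- mins_t[abs(mins_t - t) <= radius_s]
    if (!length(cand)) {
      warning(sprintf("no local minimum within %.0f s of trigger at %.1f s; left unchanged",
                      radius_s, t))
      return(t)
    }
    cand[order(abs(cand - t), cand)][1]
  }, numeric(1))
  if (!is.null(overrides)) {
    if (!all(c("trigger_index", "t_s") %in% names(overrides))) {
      stop_user("overrides must have columns trigger_index and t_s")
    }
    t_new[overrides$trigger_index] <- overrides$t_s
  }
  if (any(diff(t_new) <= 0)) {
    bad <- which(diff(t_new) <= 0)[1]
    stop_user("triggers %d and %d collide after alignment (%.1f s vs %.1f s)",
              bad, bad + 1L, t_new[bad], t_new[bad + 1L])
  }
  out <- triggers
  out$t_s <- t_new
  out
}
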
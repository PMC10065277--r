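# Time-domain HRV: RMSSD over baseline, task and ultra-short (10 s)
# pre-trigger windows, plus RR-derived mean heart rate.

#' Root mean square of successive differences (RMSSD)
#'
#' `sqrt(mean(diff(rr)^2))` with the denominator equal to the number of
#' successive differences (N - 1 for N intervals) -- the standard time-domain
#' HRV index, robust down to ~10 s windows.
#'
#' @param rr_values numeric vector of interbeat intervals (ms).
#' @return RMSSD in ms; `NA_real_` when fewer than 2 intervals are supplied
#'   (an invalid measure, not an error).
#' @examples
#' rmssd(c(1000, 1010, 990, 1005))  # sqrt(725/3) = 15.546
#' @export
rmssd <- function(rr_values) {
  if (length(rr_values) < 2L) return(NA_real_)
  sqrt(mean(diff(rr_values)^2))
}

#' HRV measure over a time window
#'
#' Selects the beats whose reconstructed timestamps fall in the half-open
#' window `(start_s, end_s]` (so a beat on a boundary belongs to exactly one
#' of two adjacent windows) and computes RMSSD plus the beat-weighted mean
#' heart rate `60000 / mean(rr)`.
#'
#' @param stream a `timestamped_rr`.
#' @param start_s,end_s window bounds in seconds, `start_s < end_s`.
#' @return A one-row data frame of class `hrv_measure` with columns
#'   `window_start`, `window_end`, `rmssd`, `mean_hr`, `n_beats`, `valid`.
#'   Fewer than 2 beats in the window yields `valid = FALSE` (not an error).
#' @export
window_rmssd <- function(stream, start_s, end_s) {
  stopifnot(inherits(stream, "timestamped_rr"))
  if (!is_scalar_number(start_s) || !is_scalar_number(end_s) || start_s >= end_s) {
    stop_user("window bounds must satisfy start_s < end_s")
  }
  sel <- stream$t_s > start_s & stream$t_s <= end_s
  rr <- stream$rr_ms[sel]
  n <- length(rr)
  valid <- n >= 2L
  out <- data.frame(
    window_start = start_s, window_end = end_s,
    rmssd = if (valid) rmssd(rr) else NA_real_,
    mean_hr = if (n >= 1L) 60000 / mean(rr) else NA_real_,
    n_beats = n, valid = valid)
  class(out) <- c("hrv_measure", "data.frame")
  out
}

#' Ultra-short-term RMSSD before a trigger
#'
#' RMSSD over the `span_s` seconds preceding the moment the reported distance
#' was reached: `window_rmssd(stream, trigger_t - span_s, trigger_t)`. A
#' trigger within the first `span_s` seconds of the stream yields an invalid
#' measure (logged via a warning), not an error.
#'
#' @param stream a `timestamped_rr`.
#' @param trigger_t trigger time in seconds.
#' @param span_s window length in seconds (default 10).
#' @return An `hrv_measure` (see [window_rmssd()]).
#' @export
pre_trigger_rmssd <- function(stream, trigger_t, span_s = 10) {
  stopifnot(inherits(stream, "timestamped_rr"), span_s > 0)
  if (trigger_t < span_s) {
    warning(sprintf("trigger at %.1f s precedes a full %.0f s window; measure invalid",
                    trigger_t, span_s))
    out <- data.frame(window_start = trigger_t - span_s, window_end = trigger_t,
                      rmssd = NA_real_, mean_hr = NA_real_, n_beats = 0L,
                      valid = FALSE)
    class(out) <- c("hrv_measure", "data.frame")
    return(out)
  }
  window_rmssd(stream, trigger_t - span_s, trigger_t)
}
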
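#' The eight condition keys of the stop-distance paradigm
#'
#' Full crossing of eye contact (yes/no), attribution (self/other) and role
#' (active/passive), listed in paradigm order: within each eye-contact block
#' the participant first approaches actively (judging for self, then for the
#' experimenter), then stands passively (self, then other).
#'
#' @param eye_block_order character vector of length 2 giving the order of the
#'   eye-contact blocks, a permutation of `c("yes", "no")`.
#' @return A data frame with 8 rows and columns `eye_contact`, `attribution`,
#'   `role`, and a compact `key` label.
#' @examples
#' condition_keys()
#' @export
condition_keys <- function(eye_block_order = c("yes", "no")) {
  if (!setequal(eye_block_order, c("yes", "no")) || length(eye_block_order) != 2L) {
    stop_user("eye_block_order must be a permutation of c('yes', 'no')")
  }
  block <- function(eye) {
    data.frame(
      eye_contact = eye,
      attribution = c("self", "other", "self", "other"),
      role        = c("active", "active", "passive", "passive"),
      stringsAsFactors = FALSE
    )
  }
  out <- rbind(block(eye_block_order[1]), block(eye_block_order[2]))
  out$key <- paste(out$eye_contact, out$attribution, out$role, sep = "_")
  out
}

#' Simulation configuration for synthetic stop-distance sessions
#'
#' Defaults are the published group-level presets of the study design this
#' package emulates: 22 autistic (ASD) and 21 control (CP) participants;
#' preferred-distance means/SDs of 103.670/47.322 cm (ASD) and 67.690/28.589 cm
#' (CP); baseline RMSSD 32.90 (15.97) ms vs 48.26 (26.68) ms and task RMSSD
#' 26.57 (8.79) ms vs 31.60 (16.11) ms; mean RR intervals derived from the
#' printed baseline heart rates (662 ms ASD, 689 ms CP). Values not fixed by
#' the design (approach speed, hold duration, artifact rate, sensor noise) have
#' documented defaults; see the methods vignette.
#'
#' @param n_asd,n_cp participants per group (>= 1).
#' @param distance_mean_cm,distance_sd_cm named numeric vectors (`asd`, `cp`),
#'   person-level mean preferred distance in cm.
#' @param baseline_rmssd_ms,task_rmssd_ms named lists (`asd`, `cp`), each a
#'   `c(mean =, sd =)` pair in ms for the person-level RMSSD target.
#' @param mean_rr_ms named numeric vector (`asd`, `cp`), group mean RR in ms.
#' @param artifact_rate per-beat probability of an artifact spike, in `[0, 1]`.
#' @param approach_speed_cm_s walking speed during approach/return segments.
#' @param hold_duration_s time spent holding the stop distance per episode.
#' @param baseline_duration_s stationary baseline before the task (>= 60 s).
#' @param sample_rate_hz raw proximity sampling rate. The device streams at
#'   ~1 kHz; the default 10 Hz is behaviourally equivalent after
#'   median-per-second resampling and keeps simulations light.
#' @param noise_cm half-width of the uniform proximity measurement noise
#'   (sensor precision is approximately +/-10 cm); 0 disables noise.
#' @param within_sd_cm within-person between-condition SD of true stop
#'   distances, cm.
#' @param rr_person_sd_ms person-level jitter of mean RR around the group mean.
#' @param episode_order optional 8-row data frame as returned by
#'   [condition_keys()]; `NULL` randomises the eye-contact block order per
#'   participant (as in the original design).
#' @param covariate_rates named probabilities for the yes/no covariates
#'   `caffeine`, `smoking`, `exercise` in the metadata table.
#' @param seed integer seed for [simulate_cohort()]; `NULL` uses the current
#'   RNG state.
#' @return An object of class `sim_config` (a validated list).
#' @seealso [simulate_session()], [simulate_cohort()]
#' @export
sim_config <- function(n_asd = 22, n_cp = 21,
                       distance_mean_cm = c(asd = 103.670, cp = 67.690),
                       distance_sd_cm   = c(asd = 47.322, cp = 28.589),
                       baseline_rmssd_ms = list(asd = c(mean = 32.90, sd = 15.97),
                                                cp  = c(mean = 48.26, sd = 26.68)),
                       task_rmssd_ms     = list(asd = c(mean = 26.57, sd = 8.79),
                                                cp  = c(mean = 31.60, sd = 16.11)),
                       mean_rr_ms = c(asd = 662, cp = 689),
                       artifact_rate = 0.02,
                       approach_speed_cm_s = 50,
                       hold_duration_s = 10,
                       baseline_duration_s = 90,
                       sample_rate_hz = 10,
                       noise_cm = 10,
                       within_sd_cm = 10,
                       rr_person_sd_ms = 40,
                       episode_order = NULL,
                       covariate_rates = c(caffeine = 0.8, smoking = 0.15,
                                           exercise = 0.8),
                       seed = NULL) {
  stopifnot(n_asd >= 1, n_cp >= 1)
  for (v in list(distance_mean_cm, distance_sd_cm, mean_rr_ms)) {
    if (!all(c("asd", "cp") %in% names(v)) || any(v[c("asd", "cp")] < 0)) {
      stop_user("group presets must be named vectors (asd, cp) with non-negative values")
    }
  }
  for (l in list(baseline_rmssd_ms, task_rmssd_ms)) {
    ok <- all(c("asd", "cp") %in% names(l)) &&
      all(vapply(l, function(x) all(c("mean", "sd") %in% names(x)) && all(x >= 0),
                 logical(1)))
    if (!ok) stop_user("RMSSD presets must be lists (asd, cp) of c(mean=, sd=) >= 0")
  }
  if (!is_scalar_number(artifact_rate) || artifact_rate < 0 || artifact_rate > 1) {
    stop_user("artifact_rate must be a probability in [0, 1]")
  }
  stopifnot(approach_speed_cm_s > 0, hold_duration_s > 0,
            baseline_duration_s >= 60, sample_rate_hz > 0,
            noise_cm >= 0, within_sd_cm >= 0, rr_person_sd_ms >= 0)
  if (!is.null(episode_order)) validate_episode_order(episode_order)
  structure(
    list(n_asd = as.integer(n_asd), n_cp = as.integer(n_cp),
         distance_mean_cm = distance_mean_cm, distance_sd_cm = distance_sd_cm,
         baseline_rmssd_ms = baseline_rmssd_ms, task_rmssd_ms = task_rmssd_ms,
         mean_rr_ms = mean_rr_ms, artifact_rate = artifact_rate,
         approach_speed_cm_s = approach_speed_cm_s,
         hold_duration_s = hold_duration_s,
         baseline_duration_s = baseline_duration_s,
         sample_rate_hz = sample_rate_hz, noise_cm = noise_cm,
         within_sd_cm = within_sd_cm, rr_person_sd_ms = rr_person_sd_ms,
         episode_order = episode_order, covariate_rates = covariate_rates,
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "sim_config"
  )
}

validate_episode_order <- function(order) {
  need <- c("eye_contact", "attribution", "role")
  if (!is.data.frame(order) || nrow(order) != 8L || !all(need %in% names(order))) {
    stop_user("episode_order must be an 8-row data frame with columns %s",
              paste(need, collapse = ", "))
  }
  keys <- paste(order$eye_contact, order$attribution, order$role, sep = "_")
  full <- condition_keys()$key
  if (!setequal(keys, full) || anyDuplicated(keys)) {
    stop_user("episode_order must cover all 8 condition keys exactly once")
  }
  # active/passive nested within each eye-contact block
  for (eye in unique(order$eye_contact)) {
    blk <- order[order$eye_contact == eye, ]
    if (nrow(blk) != 4L || is.unsorted(match(blk$role, c("active", "passive")))) {
      stop_user("within each eye-contact block the active episodes must precede the passive ones")
    }
  }
  invisible(order)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> ", x$n_asd, " ASD + ", x$n_cp, " CP participants\n", sep = "")
  cat(sprintf("  distance: ASD %.1f (%.1f) cm, CP %.1f (%.1f) cm\n",
              x$distance_mean_cm[["asd"]], x$distance_sd_cm[["asd"]],
              x$distance_mean_cm[["cp"]], x$distance_sd_cm[["cp"]]))
  cat(sprintf("  RMSSD baseline/task: ASD %.1f/%.1f ms, CP %.1f/%.1f ms\n",
              x$baseline_rmssd_ms$asd[["mean"]], x$task_rmssd_ms$asd[["mean"]],
              x$baseline_rmssd_ms$cp[["mean"]], x$task_rmssd_ms$cp[["mean"]]))
  cat(sprintf("  artifact rate %.3f/beat, approach %.0f cm/s, hold %.0f s, noise +/-%.0f cm\n",
              x$artifact_rate, x$approach_speed_cm_s, x$hold_duration_s, x$noise_cm))
  invisible(x)
}
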
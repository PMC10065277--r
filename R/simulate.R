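# Synthetic data generator: RR streams, proximity traces, triggers, cohorts.

#' Simulate an RR-interval stream with a known RMSSD target
#'
#' Interbeat intervals are drawn as `mean_rr_ms + e_i` with independent
#' Gaussian `e_i`, `sd = target_rmssd_ms / sqrt(2)`, so the expected RMSSD of
#' the stream equals the target (successive-difference variance is `2*sd^2`).
#' Beats are generated until their cumulative time reaches `duration_s`.
#' With probability `artifact_rate` a beat is replaced by a spike drawn
#' uniformly from 1200--2000 ms, guaranteed to trip the >= 1200 ms cleaning
#' rule downstream; spike positions are recorded in the `artifact_idx`
#' attribute as ground truth for recovery tests.
#'
#' @param duration_s stream duration in seconds (> 0).
#' @param mean_rr_ms mean interbeat interval in ms (> 0).
#' @param target_rmssd_ms RMSSD target in ms (>= 0); 0 yields a constant series.
#' @param artifact_rate per-beat spike probability in `[0, 1]`.
#' @param seed optional integer seed; the caller's RNG state is restored.
#' @param recording_start `POSIXct` recording start encoded in export filenames.
#' @return An `rr_series` object (see [new_rr_series()]) with attribute
#'   `artifact_idx` (integer positions of injected spikes).
#' @examples
#' s <- simulate_rr_series(60, 800, 30, seed = 1)
#' rmssd(rr_values(s))
#' @export
simulate_rr_series <- function(duration_s, mean_rr_ms, target_rmssd_ms,
                               artifact_rate = 0, seed = NULL,
                               recording_start = as.POSIXct("2019-11-03 10:00:00",
                                                            tz = "UTC")) {
  if (!is_scalar_number(duration_s) || duration_s <= 0) {
    stop_user("duration_s must be a positive number, got %s", format(duration_s))
  }
  if (!is_scalar_number(mean_rr_ms) || mean_rr_ms <= 0) {
    stop_user("mean_rr_ms must be a positive number, got %s", format(mean_rr_ms))
  }
  stopifnot(target_rmssd_ms >= 0, artifact_rate >= 0, artifact_rate <= 1)
  with_seed(seed, {
    sd_ms <- target_rmssd_ms / sqrt(2)
    total_ms <- duration_s * 1000
    rr <- numeric(0)
    while (sum(rr) < total_ms) {
      n_more <- max(16L, ceiling((total_ms - sum(rr)) / mean_rr_ms))
      block <- stats::rnorm(n_more, mean_rr_ms, sd_ms)
      block <- pmax(block, mean_rr_ms * 0.2)  # keep intervals physical (> 0)
      rr <- c(rr, block)
    }
    rr <- rr[seq_len(which(cumsum(rr) >= total_ms)[1])]
    artifact_idx <- integer(0)
    if (artifact_rate > 0) {
      hit <- stats::runif(length(rr)) < artifact_rate
      artifact_idx <- which(hit)
      rr[hit] <- stats::runif(sum(hit), 1200, 2000)
    }
    out <- new_rr_series(rr, recording_start)
    attr(out, "artifact_idx") <- artifact_idx
    out
  })
}

# Piecewise-linear position profile of one session; returns vertices and the
# per-episode arrival/leave times at the stop distance.
session_profile <- function(stops_cm, config) {
  speed <- config$approach_speed_cm_s
  hold <- config$hold_duration_s
  t <- config$baseline_duration_s
  vt <- c(0, t); vx <- c(500, 500)
  arrive <- leave <- numeric(length(stops_cm))
  for (i in seq_along(stops_cm)) {
    d <- stops_cm[i]
    travel <- (500 - d) / speed
    arrive[i] <- t + travel
    leave[i] <- arrive[i] + hold
    t <- leave[i] + travel
    vt <- c(vt, arrive[i], leave[i], t)
    vx <- c(vx, d, d, 500)
  }
  list(vt = vt, vx = vx, arrive = arrive, leave = leave, end = t)
}

#' Simulate one complete stop-distance session
#'
#' Produces the full measurement set for one participant: an RR stream
#' spanning the session (baseline-RMSSD segment followed by a task-RMSSD
#' segment), a proximity trace starting at 500 cm with a stationary baseline
#' and eight approach--hold--return episodes, the eight labelled trigger
#' times, and the planted ground truth. Per-episode stop distances are drawn
#' from the group's truncated normal (lower bound 30 cm, the intimate-zone
#' floor) around a person-level mean; uniform measurement noise of at most
#' `+/- noise_cm` is added to every raw proximity sample.
#'
#' @param group_label `"ASD"` or `"CP"`.
#' @param config a [sim_config()].
#' @param seed optional integer seed.
#' @return A list of class `prox_session` with elements `rr` (`rr_series`),
#'   `trace` (`proximity_trace`), `triggers` (`trigger_set`) and `truth`
#'   (planted parameters: `stop_distance_cm` per condition key,
#'   `baseline_rmssd_ms`, `task_rmssd_ms`, `mean_rr_ms`, `artifact_idx`,
#'   `task_start_s`, `episode_order`).
#' @export
simulate_session <- function(group_label, config = sim_config(), seed = NULL) {
  if (!group_label %in% c("ASD", "CP")) {
    stop_user("group_label must be 'ASD' or 'CP', got '%s'", group_label)
  }
  g <- tolower(group_label)
  with_seed(seed, {
    order <- config$episode_order
    if (is.null(order)) order <- condition_keys(sample(c("yes", "no")))
    validate_episode_order(order)

    person_mean <- rnorm_trunc(1, config$distance_mean_cm[[g]],
                               config$distance_sd_cm[[g]], lower = 30, upper = 450)
    stops <- rnorm_trunc(8, person_mean, config$within_sd_cm,
                         lower = 30, upper = 480)

    prof <- session_profile(stops, config)
    dt <- 1 / config$sample_rate_hz
    grid <- seq(0, prof$end, by = dt)
    pos <- stats::approx(prof$vt, prof$vx, xout = grid, rule = 2)$y
    if (config$noise_cm > 0) {
      pos <- pmax(0, pos + stats::runif(length(pos), -config$noise_cm,
                                        config$noise_cm))
      pos[1] <- 500  # the trace is anchored at the 500 cm start mark
    }
    # hold samples carry the stop distance exactly (before noise); the planted
    # trigger is the first on-grid sample at the minimum
    trigger_t <- vapply(prof$arrive, function(a) grid[grid >= a][1], numeric(1))
    trace <- new_proximity_trace(round(grid * 1000), pos, resolution = "raw")

    base_target <- rnorm_trunc(1, config$baseline_rmssd_ms[[g]][["mean"]],
                               config$baseline_rmssd_ms[[g]][["sd"]], lower = 3)
    task_target <- rnorm_trunc(1, config$task_rmssd_ms[[g]][["mean"]],
                               config$task_rmssd_ms[[g]][["sd"]], lower = 3)
    person_rr <- rnorm_trunc(1, config$mean_rr_ms[[g]], config$rr_person_sd_ms,
                             lower = 400, upper = 1100)
    rr_base <- simulate_rr_series(config$baseline_duration_s, person_rr,
                                  base_target, config$artifact_rate)
    rr_task <- simulate_rr_series(prof$end - config$baseline_duration_s + 15,
                                  person_rr, task_target, config$artifact_rate)
    values <- c(rr_values(rr_base), rr_values(rr_task))
    rr <- new_rr_series(values, rr_base$recording_start)
    attr(rr, "artifact_idx") <- c(attr(rr_base, "artifact_idx"),
                                  attr(rr_task, "artifact_idx") +
                                    length(rr_values(rr_base)))

    triggers <- new_trigger_set(trigger_t, order)
    truth <- list(
      stop_distance_cm = stats::setNames(stops, order$key),
      person_mean_cm = person_mean,
      baseline_rmssd_ms = base_target, task_rmssd_ms = task_target,
      mean_rr_ms = person_rr,
      artifact_idx = attr(rr, "artifact_idx"),
      task_start_s = config$baseline_duration_s,
      trigger_t_s = trigger_t,
      episode_order = order
    )
    structure(list(rr = rr, trace = trace, triggers = triggers, truth = truth),
              class = "prox_session")
  })
}

#' Simulate a full cohort of sessions plus metadata
#'
#' Generates `n_asd + n_cp` independent sessions and a metadata table with
#' group membership and yes/no lifestyle covariates (caffeine, smoking,
#' exercise) sampled at the configured rates. All randomness flows through the
#' config seed: identical seeds give identical cohorts.
#'
#' @param config a [sim_config()].
#' @return A list of class `prox_cohort` with `sessions` (named list of
#'   `prox_session`), `metadata` (data frame: `participant`, `group`,
#'   covariates) and `config`.
#' @examples
#' co <- simulate_cohort(sim_config(n_asd = 2, n_cp = 2, seed = 1))
#' co$metadata
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    n <- config$n_asd + config$n_cp
    ids <- sprintf("P%02d", seq_len(n))
    groups <- c(rep("ASD", config$n_asd), rep("CP", config$n_cp))
    sessions <- stats::setNames(
      lapply(seq_len(n), function(i) simulate_session(groups[i], config)), ids)
    covs <- lapply(config$covariate_rates, function(p) {
      ifelse(stats::runif(n) < p, "yes", "no")
    })
    metadata <- data.frame(participant = ids, group = groups,
                           covs, stringsAsFactors = FALSE)
    structure(list(sessions = sessions, metadata = metadata, config = config),
              class = "prox_cohort")
  })
}

#' @export
print.prox_session <- function(x, ...) {
  cat("<prox_session> ", length(rr_values(x$rr)), " beats, ",
      nrow(x$trace), " proximity samples, 8 episodes\n", sep = "")
  invisible(x)
}

#' @export
print.prox_cohort <- function(x, ...) {
  cat("<prox_cohort> ", sum(x$metadata$group == "ASD"), " ASD + ",
      sum(x$metadata$group == "CP"), " CP participants\n", sep = "")
  invisible(x)
}
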
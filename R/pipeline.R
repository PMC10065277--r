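# One-command orchestration: simulate or ingest a cohort, run
# preprocessing -> HRV -> paradigm -> statistics, write a reproducible bundle.

#' Pipeline configuration
#'
#' Defaults mirror the measurement protocol: a 60 s baseline HRV window from
#' the start of the recording, a 60 s task window one minute after task onset
#' (+60 s to +120 s), and 10 s ultra-short windows before each trigger.
#'
#' @param mode `"simulate"` (generate a cohort from `sim`) or `"ingest"`
#'   (read a cohort directory written in the package dialects).
#' @param sim a [sim_config()] (simulate mode; default presets if `NULL`).
#' @param input_dir cohort directory (ingest mode).
#' @param out_dir output directory for the report bundle.
#' @param baseline_window `c(start, end)` seconds of the baseline HRV window.
#' @param task_offset `c(start, end)` seconds of the task HRV window relative
#'   to task onset.
#' @param pre_trigger_span_s ultra-short window length, seconds.
#' @param threshold_cm episode separation threshold for minima detection.
#' @param alpha significance level used in reports.
#' @param n_boot bootstrap resamples for the regression.
#' @param seed integer seed governing all randomness of the run.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("simulate", "ingest"), sim = NULL,
                            input_dir = NULL, out_dir = tempfile("proxhrv_run_"),
                            baseline_window = c(0, 60), task_offset = c(60, 120),
                            pre_trigger_span_s = 10, threshold_cm = 300,
                            alpha = 0.05, n_boot = 1000, seed = 1) {
  mode <- match.arg(mode)
  if (mode == "simulate") {
    if (!is.null(input_dir)) stop_user("simulate mode takes no input_dir")
    if (is.null(sim)) sim <- sim_config(seed = seed)
    if (is.null(sim$seed)) sim$seed <- as.integer(seed)
  } else {
    if (is.null(input_dir)) stop_user("ingest mode requires input_dir")
    if (!is.null(sim)) stop_user("ingest mode takes no sim config")
  }
  stopifnot(diff(baseline_window) > 0, diff(task_offset) > 0,
            pre_trigger_span_s > 0, threshold_cm > 0, n_boot >= 1)
  structure(list(mode = mode, sim = sim, input_dir = input_dir,
                 out_dir = out_dir, baseline_window = baseline_window,
                 task_offset = task_offset,
                 pre_trigger_span_s = pre_trigger_span_s,
                 threshold_cm = threshold_cm, alpha = alpha,
                 n_boot = as.integer(n_boot), seed = as.integer(seed)),
            class = "pipeline_config")
}

process_participant <- function(id, sess, config) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_user("stage '%s' failed for participant %s: %s", name, id,
                conditionMessage(e))
    })
  }
  trace1 <- stage("resample", resample_proximity(sess$trace))
  triggers <- stage("detect_minima",
                    detect_episode_minima(trace1, sess$triggers[
                      c("eye_contact", "attribution", "role")],
                      threshold_cm = config$threshold_cm))
  raw_dist <- stage("extract_distances",
                    extract_condition_distances(trace1, triggers, id))
  pooled <- stage("pool", pool_active_passive(raw_dist))

  hrv <- NULL
  clean <- NULL
  if (!is.null(sess$rr)) {
    stream <- stage("timestamps", reconstruct_timestamps(sess$rr))
    cleaned <- stage("artifact_correction", correct_artifacts(stream))
    stream <- cleaned$stream
    clean <- cleaned$report
    task_start <- stage("task_start", detect_task_start(trace1))
    base <- window_rmssd(stream, config$baseline_window[1],
                         config$baseline_window[2])
    task <- window_rmssd(stream, task_start + config$task_offset[1],
                         task_start + config$task_offset[2])
    pre <- do.call(rbind, lapply(seq_len(nrow(triggers)), function(i) {
      suppressWarnings(
        pre_trigger_rmssd(stream, triggers$t_s[i], config$pre_trigger_span_s))
    }))
    pre <- cbind(triggers[c("eye_contact", "attribution", "role")], pre)
    pre <- suppressWarnings(standardize_hrv(pre, base))
    fixed <- data.frame(eye_contact = NA, attribution = NA, role = NA,
                        rbind(base, task), hrv_std = NA_real_)
    hrv <- cbind(participant = id,
                 window_type = c("baseline", "task", rep("pre_trigger", nrow(pre))),
                 rbind(fixed, pre[names(fixed)]))
  }
  list(raw = raw_dist, pooled = pooled, hrv = hrv, clean = clean)
}

#' Run the full analysis pipeline
#'
#' Simulates or ingests a cohort, then runs resampling, episode detection,
#' distance extraction and pooling, artifact correction, windowed and
#' pre-trigger HRV, baseline standardisation, the missing-data policy, and
#' the statistics battery. Writes a reproducible bundle (CSV/JSON plus a run
#' log) to `config$out_dir`; reruns with the same config and seed are
#' bit-identical.
#'
#' @param config a [pipeline_config()].
#' @return The report bundle, invisibly: a list with `distances`, `hrv`,
#'   `stats`, `cleaning`, `hrv_ids`, `out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cohort <- if (config$mode == "simulate") {
    simulate_cohort(config$sim)
  } else {
    read_cohort(config$input_dir)
  }
  meta <- cohort$metadata
  log_lines <- c(sprintf("proxhrv %s", as.character(utils::packageVersion("proxhrv"))),
                 sprintf("mode=%s seed=%d participants=%d", config$mode,
                         config$seed, nrow(meta)),
                 sprintf("baseline_window=%g-%g task_offset=%g-%g pre_span=%g threshold=%g alpha=%g n_boot=%d",
                         config$baseline_window[1], config$baseline_window[2],
                         config$task_offset[1], config$task_offset[2],
                         config$pre_trigger_span_s, config$threshold_cm,
                         config$alpha, config$n_boot))

  per <- lapply(meta$participant, function(id) {
    res <- process_participant(id, cohort$sessions[[id]], config)
    log_lines <<- c(log_lines, sprintf(
      "participant %s: 8 episodes, %s", id,
      if (is.null(res$hrv)) "no RR record" else sprintf(
        "%d+%d beats replaced", res$clean$n_replaced_threshold,
        res$clean$n_replaced_zscore)))
    res
  })
  names(per) <- meta$participant

  distances <- do.call(rbind, c(lapply(per, `[[`, "raw"),
                                lapply(per, `[[`, "pooled")))
  rownames(distances) <- NULL
  hrv <- do.call(rbind, lapply(per, `[[`, "hrv"))
  rownames(hrv) <- NULL

  dropped <- drop_incomplete(cohort, config$baseline_window,
                             config$task_offset, config$pre_trigger_span_s)
  for (nm in names(dropped$report$participants_dropped)) {
    log_lines <- c(log_lines, sprintf("dropped from HRV analyses: %s (%s)",
                                      nm, dropped$report$participants_dropped[nm]))
  }

  stats_out <- compute_cohort_stats(distances, hrv, meta, dropped$hrv_ids, config)

  clean_total <- new_cleaning_report(
    n_replaced_threshold = sum(vapply(per, function(r)
      if (is.null(r$clean)) 0L else r$clean$n_replaced_threshold, integer(1))),
    n_replaced_zscore = sum(vapply(per, function(r)
      if (is.null(r$clean)) 0L else r$clean$n_replaced_zscore, integer(1))),
    participants_dropped = dropped$report$participants_dropped)

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(distances, file.path(config$out_dir, "distances.csv"),
                   row.names = FALSE)
  if (!is.null(hrv)) {
    utils::write.csv(hrv, file.path(config$out_dir, "hrv.csv"), row.names = FALSE)
  }
  jsonlite::write_json(unclass(clean_total),
                       file.path(config$out_dir, "cleaning_report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  jsonlite::write_json(stats_to_list(stats_out),
                       file.path(config$out_dir, "stats.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  utils::write.csv(stats_out$anova_distance,
                   file.path(config$out_dir, "anova_distance.csv"),
                   row.names = FALSE)
  writeLines(log_lines, file.path(config$out_dir, "run_log.txt"))

  invisible(list(distances = distances, hrv = hrv, stats = stats_out,
                 cleaning = clean_total, hrv_ids = dropped$hrv_ids,
                 out_dir = config$out_dir))
}

compute_cohort_stats <- function(distances, hrv, meta, hrv_ids, config) {
  out <- list()
  pooled <- distances[distances$role == "pooled" & !is.na(distances$distance_cm), ]
  pooled$group <- meta$group[match(pooled$participant, meta$participant)]

  out$anova_distance <- mixed_anova(pooled, "distance_cm", between = "group",
                                    within = c("eye_contact", "attribution"))

  person_mean <- stats::aggregate(distance_cm ~ participant, pooled, mean)
  person_mean$group <- meta$group[match(person_mean$participant,
                                        meta$participant)]
  grp_sizes <- table(person_mean$group)
  if (all(c("ASD", "CP") %in% names(grp_sizes)) && all(grp_sizes >= 2)) {
    out$distance_group_test <- mann_whitney_rb(
      person_mean$distance_cm[person_mean$group == "ASD"],
      person_mean$distance_cm[person_mean$group == "CP"])
    out$group_means <- stats::setNames(
      tapply(person_mean$distance_cm, person_mean$group, mean)[c("ASD", "CP")],
      c("ASD", "CP"))
  }

  for (cov in intersect(c("caffeine", "smoking", "exercise"), names(meta))) {
    tab <- table(meta$group, meta[[cov]])
    if (all(dim(tab) >= 2)) {
      out[[paste0("chisq_", cov)]] <- tryCatch(chi_square_test(tab),
                                               error = function(e) NULL)
    }
  }

  if (!is.null(hrv)) {
    bt <- hrv[hrv$window_type %in% c("baseline", "task") &
                hrv$participant %in% hrv_ids, ]
    bt$group <- meta$group[match(bt$participant, meta$participant)]
    bt$time <- bt$window_type
    if (length(unique(bt$participant)) >= 4) {
      out$anova_hrv_time <- mixed_anova(bt, "rmssd", between = "group",
                                        within = "time")
      out$posthoc_hrv_time <- bonferroni_posthoc(bt, "rmssd", "time",
                                                 family_size = 2)
    }
    pre <- hrv[hrv$window_type == "pre_trigger" & hrv$participant %in% hrv_ids &
                 !is.na(hrv$hrv_std), ]
    pre$group <- meta$group[match(pre$participant, meta$participant)]
    if (nrow(pre) && length(unique(pre$participant)) >= 4) {
      pre_pooled <- stats::aggregate(
        hrv_std ~ participant + group + eye_contact + attribution, pre, mean)
      complete_ids <- names(which(table(pre_pooled$participant) == 4))
      pre_pooled <- pre_pooled[pre_pooled$participant %in% complete_ids, ]
      if (length(complete_ids) >= 4 &&
          length(unique(pre_pooled$group)) == 2) {
        out$anova_hrv_std <- mixed_anova(pre_pooled, "hrv_std",
                                         between = "group",
                                         within = c("eye_contact", "attribution"))
        reg <- merge(pre_pooled,
                     stats::aggregate(distance_cm ~ participant + eye_contact +
                                        attribution, pooled, mean))
        if (nrow(reg) > 8) {
          reg$is_asd <- as.numeric(reg$group == "ASD")
          out$regression <- tryCatch(
            bootstrap_regression(reg$distance_cm,
                                 data.frame(hrv_std = reg$hrv_std,
                                            group = reg$is_asd,
                                            interaction = reg$hrv_std * reg$is_asd),
                                 n_boot = config$n_boot, seed = config$seed),
            error = function(e) NULL)
        }
      }
    }
  }
  out
}

stats_to_list <- function(stats_out) {
  lapply(stats_out, function(x) {
    if (is.data.frame(x)) x else if (is.list(x)) lapply(unclass(x), function(y) {
      if (is.matrix(y)) as.data.frame(y) else y
    }) else x
  })
}
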
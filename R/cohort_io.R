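# Cohort-level fixture I/O in the stream dialects: one directory per
# participant with an RR export, a proximity CSV and a trigger CSV, plus
# cohort metadata and the generating config.

#' Write a cohort to disk in the package's stream dialects
#'
#' Layout: `meta.csv`, `config.json`, and `participants/<id>/` holding the RR
#' export (`YYYY-MM-DD_HH-MM-SS.txt`), `proximity.csv` (`t_ms,distance_cm`)
#' and `triggers.csv` (`t_s,eye_contact,attribution,role`).
#'
#' @param cohort a `prox_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "prox_cohort"))
  dir.create(file.path(dir, "participants"), recursive = TRUE,
             showWarnings = FALSE)
  utils::write.csv(cohort$metadata, file.path(dir, "meta.csv"),
                   row.names = FALSE, quote = FALSE)
  if (!is.null(cohort$config)) {
    cfg <- unclass(cohort$config)
    jsonlite::write_json(cfg, file.path(dir, "config.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  for (id in names(cohort$sessions)) {
    sess <- cohort$sessions[[id]]
    pdir <- file.path(dir, "participants", id)
    dir.create(pdir, showWarnings = FALSE)
    if (!is.null(sess$rr)) write_rr_export(sess$rr, pdir)
    write_proximity(sess$trace, file.path(pdir, "proximity.csv"))
    trg <- as.data.frame(sess$triggers)
    trg$t_s <- sprintf("%.10g", trg$t_s)
    utils::write.csv(trg, file.path(pdir, "triggers.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir cohort directory.
#' @return A `prox_cohort` (sessions lacking an RR export have `rr = NULL`;
#'   planted ground truth is not part of the on-disk dialect).
#' @export
read_cohort <- function(dir) {
  meta_path <- file.path(dir, "meta.csv")
  if (!file.exists(meta_path)) stop_user("not a cohort directory (no meta.csv): %s", dir)
  metadata <- utils::read.csv(meta_path, stringsAsFactors = FALSE)
  sessions <- lapply(metadata$participant, function(id) {
    pdir <- file.path(dir, "participants", id)
    if (!dir.exists(pdir)) stop_user("missing participant directory: %s", pdir)
    rr_files <- list.files(pdir, pattern = RR_FILENAME_PATTERN, full.names = TRUE)
    rr <- if (length(rr_files)) read_rr_export(rr_files[1]) else NULL
    trace <- read_proximity(file.path(pdir, "proximity.csv"))
    trg <- utils::read.csv(file.path(pdir, "triggers.csv"),
                           stringsAsFactors = FALSE)
    triggers <- new_trigger_set(trg$t_s, trg)
    structure(list(rr = rr, trace = trace, triggers = triggers, truth = list()),
              class = "prox_session")
  })
  names(sessions) <- metadata$participant
  structure(list(sessions = sessions, metadata = metadata, config = NULL),
            class = "prox_cohort")
}
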
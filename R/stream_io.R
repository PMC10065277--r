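# Stream I/O: RR text exports, proximity CSVs, timestamp reconstruction.
#
# RR export dialect: plain text, one interbeat interval in ms per line, the
# recording start encoded in the filename as YYYY-MM-DD_HH-MM-SS.txt.
# Proximity dialect: CSV with header `t_ms,distance_cm`.

RR_FILENAME_PATTERN <- "^(\\d{4})-(\\d{2})-(\\d{2})_(\\d{2})-(\\d{2})-(\\d{2})\\.txt$"

#' Construct an RR-interval series
#'
#' @param values ordered interbeat intervals in ms, all > 0.
#' @param recording_start `POSIXct` start of the recording.
#' @return Object of class `rr_series`.
#' @export
new_rr_series <- function(values, recording_start) {
  values <- as.numeric(values)
  if (any(!is.finite(values)) || any(values <= 0)) {
    stop_user("RR intervals must all be positive finite numbers")
  }
  stopifnot(inherits(recording_start, "POSIXct"))
  structure(list(values = values, recording_start = recording_start),
            class = "rr_series")
}

#' Extract the interval values of an `rr_series`
#' @param series an `rr_series`.
#' @return Numeric vector of intervals in ms.
#' @export
rr_values <- function(series) {
  stopifnot(inherits(series, "rr_series"))
  series$values
}

#' @export
print.rr_series <- function(x, ...) {
  cat("<rr_series> ", length(x$values), " beats from ",
      format(x$recording_start, "%Y-%m-%d %H:%M:%S"),
      sprintf(" (total %.1f s)\n", sum(x$values) / 1000), sep = "")
  invisible(x)
}

#' Construct a proximity trace
#'
#' @param t_ms sample times in ms since trace start, non-decreasing.
#' @param distance_cm distances in cm, >= 0.
#' @param resolution `"raw"` (native sampling) or `"1hz"` (resampled).
#' @param interpolated optional logical flag per sample (filled bins).
#' @return A data frame of class `proximity_trace` with attribute `resolution`.
#' @export
new_proximity_trace <- function(t_ms, distance_cm, resolution = c("raw", "1hz"),
                                interpolated = NULL) {
  resolution <- match.arg(resolution)
  if (length(t_ms) && is.unsorted(t_ms)) {
    stop_user("proximity timestamps must be non-decreasing")
  }
  if (any(distance_cm < 0)) stop_user("distances must be >= 0")
  out <- data.frame(t_ms = as.numeric(t_ms), distance_cm = as.numeric(distance_cm))
  if (!is.null(interpolated)) out$interpolated <- interpolated
  structure(out, resolution = resolution,
            class = c("proximity_trace", "data.frame"))
}

trace_resolution <- function(trace) attr(trace, "resolution")

#' Construct a labelled trigger set
#'
#' @param t_s trigger times in seconds, strictly increasing, one per episode.
#' @param keys data frame with columns `eye_contact`, `attribution`, `role`
#'   (one row per trigger, pairwise distinct and exhaustive for 8 triggers).
#' @return A data frame of class `trigger_set`.
#' @export
new_trigger_set <- function(t_s, keys) {
  stopifnot(length(t_s) == nrow(keys))
  if (length(t_s) > 1 && any(diff(t_s) <= 0)) {
    stop_user("trigger times must be strictly increasing")
  }
  out <- data.frame(t_s = as.numeric(t_s),
                    eye_contact = keys$eye_contact,
                    attribution = keys$attribution,
                    role = keys$role, stringsAsFactors = FALSE)
  structure(out, class = c("trigger_set", "data.frame"))
}

#' Read a plain-text RR export
#'
#' One interval in ms per line; blank lines are skipped. The recording start
#' is parsed from the filename (`YYYY-MM-DD_HH-MM-SS.txt`) unless supplied
#' explicitly.
#'
#' @param path path to the export file.
#' @param start_time optional `POSIXct` overriding the filename timestamp (for
#'   exports whose names do not follow the pattern).
#' @param tz timezone used when parsing the filename.
#' @return An [new_rr_series()] object.
#' @export
read_rr_export <- function(path, start_time = NULL, tz = "UTC") {
  if (!file.exists(path)) stop_user("RR export not found: %s", path)
  if (is.null(start_time)) {
    fn <- basename(path)
    if (!grepl(RR_FILENAME_PATTERN, fn)) {
      stop_user(paste0(
        "cannot parse recording start from filename '%s'; expected pattern ",
        "YYYY-MM-DD_HH-MM-SS.txt (or pass start_time=)"), fn)
    }
    stamp <- sub("\\.txt$", "", fn)
    start_time <- as.POSIXct(stamp, format = "%Y-%m-%d_%H-%M-%S", tz = tz)
  }
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  if (!length(lines)) stop_user("RR export is empty: %s", path)
  values <- suppressWarnings(as.numeric(lines))
  if (anyNA(values)) {
    bad <- which(keep)[which(is.na(values))[1]]
    stop_user("non-numeric RR value at line %d of %s", bad, path)
  }
  new_rr_series(values, start_time)
}

#' Write an RR export next to the reader's dialect
#'
#' @param series an `rr_series`.
#' @param dir output directory; the filename is derived from the recording
#'   start time.
#' @return The written path, invisibly.
#' @export
write_rr_export <- function(series, dir) {
  stopifnot(inherits(series, "rr_series"))
  path <- file.path(dir, paste0(
    format(series$recording_start, "%Y-%m-%d_%H-%M-%S"), ".txt"))
  writeLines(sprintf("%.10g", rr_values(series)), path)
  invisible(path)
}

#' Reconstruct per-beat timestamps from bare RR intervals
#'
#' The export carries no per-sample timestamps; since each RR interval is the
#' time between two successive beats, elapsed time is rebuilt by appending
#' each interval to the previous beat's time: `t_i = sum(rr_1..rr_i) / 1000`
#' seconds. The first beat therefore sits at `rr_1` after recording start, and
#' the final timestamp equals the total recorded duration.
#'
#' @param series an `rr_series`.
#' @return A data frame of class `timestamped_rr` with columns `t_s`, `rr_ms`
#'   and attribute `recording_start`. An empty series gives an empty result.
#' @examples
#' s <- new_rr_series(c(1000, 500, 250), as.POSIXct("2019-11-03 10:15:00", tz = "UTC"))
#' reconstruct_timestamps(s)$t_s  # 1.0 1.5 1.75
#' @export
reconstruct_timestamps <- function(series) {
  stopifnot(inherits(series, "rr_series"))
  v <- rr_values(series)
  out <- data.frame(t_s = cumsum(v) / 1000, rr_ms = v)
  structure(out, recording_start = series$recording_start,
            class = c("timestamped_rr", "data.frame"))
}

#' Read a proximity CSV (`t_ms,distance_cm`)
#'
#' Negative distances are clamped to zero with a warning (they can arise from
#' ranging glitches); a missing column is an error. A header-only file yields
#' an empty trace with a warning.
#'
#' @param path path to the CSV.
#' @return A [new_proximity_trace()] of raw resolution.
#' @export
read_proximity <- function(path) {
  if (!file.exists(path)) stop_user("proximity file not found: %s", path)
  df <- utils::read.csv(path)
  need <- c("t_ms", "distance_cm")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop_user("proximity CSV %s lacks column(s): %s", path,
              paste(missing_cols, collapse = ", "))
  }
  if (!nrow(df)) {
    warning("proximity file has a header but no samples: ", path)
    return(new_proximity_trace(numeric(0), numeric(0), resolution = "raw"))
  }
  neg <- df$distance_cm < 0
  if (any(neg)) {
    warning(sum(neg), " negative distance sample(s) clamped to 0 in ", path)
    df$distance_cm[neg] <- 0
  }
  new_proximity_trace(df$t_ms, df$distance_cm, resolution = "raw")
}

#' Write a proximity trace as CSV
#' @param trace a `proximity_trace`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_proximity <- function(trace, path) {
  stopifnot(inherits(trace, "proximity_trace"))
  df <- data.frame(t_ms = sprintf("%.10g", trace$t_ms),
                   distance_cm = sprintf("%.10g", trace$distance_cm))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
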
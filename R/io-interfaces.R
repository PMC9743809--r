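# Readers/writers for the three plain-text stream dialects. All timestamps
# are Unix seconds (floats); intervals are half-open [start, end). Numeric
# columns are written with 17 significant digits so write/read round-trips
# are numerically lossless.

fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- ""
  out
}

write_delim_cogload <- function(df, path, sep) {
  out <- df
  for (nm in names(out)) {
    if (is.numeric(out[[nm]])) out[[nm]] <- fmt_num(out[[nm]])
  }
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE,
                     na = "")
}

#' Write an EEG recording as a Mind-Monitor-style CSV
#'
#' Dialect: comma-separated, header
#' `TimeStamp,RAW_TP9,RAW_AF7,RAW_AF8,RAW_TP10`; `TimeStamp` is Unix seconds
#' and the RAW columns are microvolts.
#'
#' @param recording An [eeg_recording()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_eeg_csv <- function(recording, path) {
  df <- data.frame(TimeStamp = rec_times(recording))
  for (ch in colnames(recording$data)) {
    df[[paste0("RAW_", ch)]] <- recording$data[, ch]
  }
  write_delim_cogload(df, path, ",")
  invisible(path)
}

#' Read a Mind-Monitor-style EEG CSV
#'
#' Expects the dialect written by [write_eeg_csv()]: a `TimeStamp` column
#' (Unix seconds) plus four `RAW_<channel>` columns. Malformed rows
#' (non-numeric or missing fields) are skipped and counted in the
#' `skipped_rows` attribute; the sampling rate is inferred from the median
#' timestamp spacing.
#'
#' @param path Input file path.
#' @return An [eeg_recording()] with attribute `skipped_rows`.
#' @export
read_eeg_csv <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE)
  chans <- sub("^RAW_", "", grep("^RAW_", names(raw), value = TRUE))
  if (!"TimeStamp" %in% names(raw) || length(chans) != 4L) {
    stop_cogload("format",
                 "expected TimeStamp plus four RAW_<channel> columns")
  }
  num <- lapply(raw[c("TimeStamp", paste0("RAW_", chans))],
                function(v) suppressWarnings(as.numeric(v)))
  ok <- Reduce(`&`, lapply(num, function(v) !is.na(v)))
  skipped <- sum(!ok)
  ts <- num$TimeStamp[ok]
  if (length(ts) < 2L) stop_cogload("format", "too few well-formed rows")
  if (is.unsorted(ts)) {
    stop_cogload("data-integrity", "timestamps must be monotone")
  }
  data <- do.call(cbind, lapply(paste0("RAW_", chans),
                                function(cl) num[[cl]][ok]))
  colnames(data) <- chans
  fs <- 1 / stats::median(diff(ts))
  out <- eeg_recording(data, fs, ts[1])
  attr(out, "skipped_rows") <- skipped
  out
}

#' Write a gaze stream as a Tobii-style TSV
#'
#' Dialect: tab-separated samples with columns `recording_timestamp` (Unix
#' seconds), `gaze_point_x`, `gaze_point_y` (pixels), `pupil_left`,
#' `pupil_right` (mm), `validity_left`, `validity_right`
#' (`Valid`/`Invalid`). Precomputed events, when present, are written to a
#' companion `*_events.tsv` with columns `kind`, `start_ts`, `end_ts`,
#' `duration_ms`.
#'
#' @param stream A [gaze_stream()].
#' @param path Sample file path; the companion event path defaults to
#'   `sub("\\\\.tsv$", "_events.tsv", path)`.
#' @param events_path Override for the event file path, or `NA` to skip
#'   writing events.
#' @return `path`, invisibly.
#' @export
write_gaze_tsv <- function(stream, path, events_path = NULL) {
  s <- stream$samples
  df <- data.frame(recording_timestamp = s$ts, gaze_point_x = s$x,
                   gaze_point_y = s$y, pupil_left = s$pupil_left,
                   pupil_right = s$pupil_right,
                   validity_left = ifelse(s$valid_left, "Valid", "Invalid"),
                   validity_right = ifelse(s$valid_right, "Valid", "Invalid"))
  write_delim_cogload(df, path, "\t")
  if (!is.null(stream$events) && !isTRUE(is.na(events_path))) {
    events_path <- events_path %||% sub("\\.tsv$", "_events.tsv", path)
    write_delim_cogload(stream$events, events_path, "\t")
  }
  invisible(path)
}

#' Read a Tobii-style gaze TSV (and companion events)
#'
#' Expects the dialect written by [write_gaze_tsv()]. Validity flags are
#' parsed strictly (`Valid`/`Invalid`); any other value is a format error.
#' If the pupil columns are absent the stream still loads with pupil
#' metrics disabled (a warning is issued). A companion `*_events.tsv` is
#' picked up automatically when present.
#'
#' @param path Sample file path.
#' @param events_path Optional explicit event file path.
#' @return A [gaze_stream()].
#' @export
read_gaze_tsv <- function(path, events_path = NULL) {
  raw <- utils::read.delim(path, colClasses = "character",
                           check.names = FALSE)
  need <- c("recording_timestamp", "gaze_point_x", "gaze_point_y",
            "validity_left", "validity_right")
  if (!all(need %in% names(raw))) {
    stop_cogload("format", paste("gaze TSV needs columns:",
                                 paste(need, collapse = ", ")))
  }
  parse_valid <- function(v) {
    if (!all(v %in% c("Valid", "Invalid"))) {
      stop_cogload("format", "validity flags must be 'Valid' or 'Invalid'")
    }
    v == "Valid"
  }
  has_pupil <- all(c("pupil_left", "pupil_right") %in% names(raw))
  if (!has_pupil) {
    warning("pupil columns absent: pupil metrics disabled for this stream")
  }
  numcol <- function(nm) suppressWarnings(as.numeric(raw[[nm]]))
  samples <- data.frame(
    ts = numcol("recording_timestamp"),
    x = numcol("gaze_point_x"), y = numcol("gaze_point_y"),
    pupil_left = if (has_pupil) numcol("pupil_left") else NA_real_,
    pupil_right = if (has_pupil) numcol("pupil_right") else NA_real_,
    valid_left = parse_valid(raw$validity_left),
    valid_right = parse_valid(raw$validity_right))
  if (!has_pupil) {
    samples$valid_left <- samples$valid_left & FALSE
    samples$valid_right <- samples$valid_right & FALSE
  }
  events <- NULL
  events_path <- events_path %||% sub("\\.tsv$", "_events.tsv", path)
  if (file.exists(events_path)) {
    ev <- utils::read.delim(events_path, check.names = FALSE)
    events <- data.frame(kind = as.character(ev$kind),
                         start_ts = as.numeric(ev$start_ts),
                         end_ts = as.numeric(ev$end_ts),
                         duration_ms = as.numeric(ev$duration_ms))
  }
  fs <- 1 / stats::median(diff(samples$ts))
  out <- gaze_stream(samples, events, fs)
  attr(out, "pupil_available") <- has_pupil
  out
}

#' Write a task log CSV
#'
#' Dialect: comma-separated with columns `id`, `n_back`, `letter`, `choice`
#' (`match`/`nonmatch`/`none`), `accuracy` (`yes`/`no`/`null`),
#' `reaction_time` (seconds, empty for timeouts), `start_unix`, `end_unix`.
#'
#' @param task_log Task-log data frame (one or more participants).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_task_log <- function(task_log, path) {
  write_delim_cogload(task_log, path, ",")
  invisible(path)
}

#' Read and integrity-check a task log CSV
#'
#' Parses the dialect of [write_task_log()], recomputes each answered
#' trial's reaction time as `end_unix - start_unix` and cross-checks it
#' against the stored column within `tolerance`; discrepancies (or
#' end-before-start rows) raise an integrity error naming the offending
#' rows.
#'
#' @param path Input file path.
#' @param tolerance Allowed |stored - recomputed| reaction-time difference,
#'   seconds (default 1 ms).
#' @return Task-log data frame with numeric timestamp columns.
#' @export
read_task_log <- function(path, tolerance = 1e-3) {
  need <- c("id", "n_back", "letter", "choice", "accuracy",
            "reaction_time", "start_unix", "end_unix")
  raw <- utils::read.csv(path, check.names = FALSE)
  if (!all(need %in% names(raw))) {
    stop_cogload("format", paste("task log needs columns:",
                                 paste(need, collapse = ", ")))
  }
  raw$start_unix <- as.numeric(raw$start_unix)
  raw$end_unix <- as.numeric(raw$end_unix)
  raw$reaction_time <- suppressWarnings(as.numeric(raw$reaction_time))
  bad_span <- which(raw$end_unix < raw$start_unix)
  if (length(bad_span)) {
    stop_cogload("integrity",
                 paste("end before start on row(s):",
                       paste(bad_span, collapse = ", ")))
  }
  answered <- raw$choice != "none" & !is.na(raw$reaction_time)
  recomputed <- raw$end_unix - raw$start_unix
  bad_rt <- which(answered &
                    abs(recomputed - raw$reaction_time) > tolerance)
  if (length(bad_rt)) {
    stop_cogload("integrity",
                 paste("stored reaction time disagrees with timestamps on",
                       "row(s):", paste(bad_rt, collapse = ", ")))
  }
  raw
}
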
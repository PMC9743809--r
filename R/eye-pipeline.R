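#' Gaze stream container
#'
#' Holds gaze samples (and, optionally, precomputed fixation/saccade events)
#' for one recording. Samples carry per-eye pupil diameters and validity
#' flags; invalid samples have `NA` pupil and gaze coordinates.
#'
#' @param samples Data frame with columns `ts` (Unix seconds, nondecreasing),
#'   `x`, `y` (screen pixels), `pupil_left`, `pupil_right` (mm),
#'   `valid_left`, `valid_right` (logical).
#' @param events Optional data frame with columns `kind`
#'   (`"fixation"`/`"saccade"`), `start_ts`, `end_ts`, `duration_ms`.
#' @param sampling_rate Nominal sampling rate, Hz.
#' @return An object of class `gaze_stream`.
#' @export
gaze_stream <- function(samples, events = NULL, sampling_rate = 60) {
  need <- c("ts", "x", "y", "pupil_left", "pupil_right",
            "valid_left", "valid_right")
  if (!all(need %in% names(samples))) {
    stop_cogload("format", paste("gaze samples need columns:",
                                 paste(need, collapse = ", ")))
  }
  if (is.unsorted(samples$ts)) {
    stop_cogload("data-integrity", "gaze timestamps must be nondecreasing")
  }
  ok <- samples$valid_left & !is.na(samples$pupil_left)
  if (any(samples$pupil_left[ok] <= 0)) {
    stop_cogload("data-integrity", "valid pupil diameters must be > 0")
  }
  if (!is.null(events) && nrow(events)) {
    if (any(events$end_ts <= events$start_ts)) {
      stop_cogload("data-integrity", "event durations must be > 0")
    }
  }
  structure(list(samples = samples, events = events,
                 sampling_rate = sampling_rate),
            class = "gaze_stream")
}

#' @export
print.gaze_stream <- function(x, ...) {
  n <- nrow(x$samples)
  cat(sprintf("Gaze stream: %d samples @ %g Hz (%.1f s), %s events\n",
              n, x$sampling_rate,
              if (n) diff(range(x$samples$ts)) else 0,
              if (is.null(x$events)) "no" else nrow(x$events)))
  invisible(x)
}

#' Velocity-threshold (I-VT) fixation and saccade detection
#'
#' Classifies inter-sample gaze velocities against a deg/s threshold:
#' contiguous below-threshold runs become fixations (kept when at least
#' `min_fixation` ms long), above-threshold runs become saccades. Invalid
#' samples and timestamp gaps break events.
#'
#' @param stream A [gaze_stream()].
#' @param velocity_threshold Saccade velocity threshold, deg/s.
#' @param min_fixation Minimum fixation duration, ms; shorter
#'   below-threshold runs are discarded.
#' @param px_per_deg Screen geometry: pixels per degree of visual angle.
#'   Required to express velocities in deg/s.
#' @param max_gap Maximum inter-sample spacing, seconds, before a run is
#'   broken (default 2.5 nominal sample periods).
#' @return Data frame of events (`kind`, `start_ts`, `end_ts`,
#'   `duration_ms`), possibly empty.
#' @export
ivt_detect <- function(stream, velocity_threshold = 30, min_fixation = 60,
                       px_per_deg = NULL, max_gap = NULL) {
  if (is.null(px_per_deg) || !is.finite(px_per_deg) || px_per_deg <= 0) {
    stop_cogload("configuration",
                 "px_per_deg geometry is required for a deg/s threshold")
  }
  s <- stream$samples
  valid <- s$valid_left & s$valid_right & !is.na(s$x) & !is.na(s$y)
  empty <- data.frame(kind = character(), start_ts = numeric(),
                      end_ts = numeric(), duration_ms = numeric())
  if (sum(valid) < 2L) return(empty)
  max_gap <- max_gap %||% (2.5 / stream$sampling_rate)
  v <- s[valid, , drop = FALSE]
  dt <- diff(v$ts)
  vel <- sqrt(diff(v$x)^2 + diff(v$y)^2) / px_per_deg / pmax(dt, 1e-9)
  state <- ifelse(vel > velocity_threshold, "saccade", "fixation")
  state[dt > max_gap] <- NA  # gap: no event spans it
  r <- rle(state)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  evs <- list()
  for (k in seq_along(r$values)) {
    kind <- r$values[k]
    if (is.na(kind)) next
    t0 <- v$ts[starts[k]]
    t1 <- v$ts[ends[k] + 1L]  # segment k spans samples starts[k]..ends[k]+1
    dur <- (t1 - t0) * 1000
    if (kind == "fixation" && dur < min_fixation) next
    evs[[length(evs) + 1L]] <- data.frame(kind = kind, start_ts = t0,
                                          end_ts = t1, duration_ms = dur)
  }
  if (length(evs) == 0L) return(empty)
  out <- do.call(rbind, evs)
  rownames(out) <- NULL
  out
}

#' Fraction of valid gaze samples
#'
#' The tracker's capture rate: valid samples / total samples. The default
#' policy requires both eyes valid; per-eye policies are available.
#'
#' @param stream A [gaze_stream()].
#' @param policy `"both"`, `"either"`, `"left"` or `"right"`.
#' @return Scalar in `[0, 1]` with attributes `n_valid` and `n_total`.
#' @export
capture_rate <- function(stream, policy = c("both", "either", "left", "right")) {
  policy <- match.arg(policy)
  s <- stream$samples
  if (nrow(s) == 0L) {
    stop_cogload("insufficient-data", "gaze stream is empty")
  }
  ok <- switch(policy,
               both = s$valid_left & s$valid_right,
               either = s$valid_left | s$valid_right,
               left = s$valid_left,
               right = s$valid_right)
  structure(sum(ok) / nrow(s), n_valid = sum(ok), n_total = nrow(s))
}

#' Per-eye resting pupil baseline
#'
#' Mean pupil diameter per eye over the valid samples of a rest interval
#' (by default the session's eyes-open rest); workload metrics are reported
#' as dilations relative to this baseline.
#'
#' @param stream A [gaze_stream()].
#' @param rest Length-2 numeric `c(start, end)`, Unix seconds.
#' @param min_valid Minimum valid samples required per eye.
#' @return Object of class `pupil_baseline`: list with `left`, `right` (mm)
#'   and the source `window`.
#' @export
pupil_baseline <- function(stream, rest, min_valid = 10L) {
  s <- stream$samples
  idx <- in_interval(s$ts, rest[1], rest[2])
  l <- s$pupil_left[idx][s$valid_left[idx]]
  r <- s$pupil_right[idx][s$valid_right[idx]]
  l <- l[!is.na(l)]; r <- r[!is.na(r)]
  if (length(l) < min_valid || length(r) < min_valid) {
    stop_cogload("insufficient-data",
                 sprintf("need >= %d valid rest samples per eye", min_valid))
  }
  structure(list(left = mean(l), right = mean(r), window = as.numeric(rest)),
            class = "pupil_baseline")
}

#' @export
print.pupil_baseline <- function(x, ...) {
  cat(sprintf("Pupil baseline: left %.3f mm, right %.3f mm (window %.1f-%.1f)\n",
              x$left, x$right, x$window[1], x$window[2]))
  invisible(x)
}

#' Per-interval eye-movement and pupillometry workload metrics
#'
#' For each stimulus interval, computes the ten workload measures: mean and
#' maximum baseline-subtracted pupil dilation per eye (mm), mean and maximum
#' fixation duration (ms), fixations per second, mean and maximum saccade
#' duration (ms), and saccades per second. Events are assigned to the
#' interval containing their start time; metrics with no contributing
#' samples/events are `NA` (flagged, never zero). Raw mean diameters are
#' included alongside the dilations.
#'
#' @param stream A [gaze_stream()].
#' @param intervals Data frame with columns `start`, `end` (Unix seconds);
#'   optional `trial_index`, `condition` columns are carried through.
#' @param baseline A [pupil_baseline()].
#' @param events Event data frame; defaults to the stream's own events.
#' @return Data frame, one row per interval, class `interval_eye_metrics`.
#' @export
interval_metrics <- function(stream, intervals, baseline, events = NULL) {
  events <- events %||% stream$events
  if (is.null(events)) {
    stop_cogload("invalid-input",
                 "no events: supply `events` or run ivt_detect() first")
  }
  s <- stream$samples
  out <- lapply(seq_len(nrow(intervals)), function(i) {
    start <- intervals$start[i]; end <- intervals$end[i]
    len <- end - start
    idx <- in_interval(s$ts, start, end)
    dl <- s$pupil_left[idx][s$valid_left[idx]] - baseline$left
    dr <- s$pupil_right[idx][s$valid_right[idx]] - baseline$right
    dl <- dl[!is.na(dl)]; dr <- dr[!is.na(dr)]
    fx <- events[events$kind == "fixation" &
                   events$start_ts >= start & events$start_ts < end, ]
    sc <- events[events$kind == "saccade" &
                   events$start_ts >= start & events$start_ts < end, ]
    m <- function(x) if (length(x)) mean(x) else NA_real_
    mx <- function(x) if (length(x)) max(x) else NA_real_
    data.frame(
      trial_index = intervals$trial_index[i] %||% i,
      condition = intervals$condition[i] %||% NA_integer_,
      start = start, end = end,
      avg_pupil_dilation_left = m(dl), avg_pupil_dilation_right = m(dr),
      max_pupil_dilation_left = mx(dl), max_pupil_dilation_right = mx(dr),
      avg_pupil_diameter_left = m(dl + baseline$left),
      avg_pupil_diameter_right = m(dr + baseline$right),
      avg_fixation_duration = m(fx$duration_ms),
      max_fixation_duration = mx(fx$duration_ms),
      fixation_number_per_second = nrow(fx) / len,
      avg_saccade_duration = m(sc$duration_ms),
      max_saccade_duration = mx(sc$duration_ms),
      saccade_number_per_second = nrow(sc) / len,
      n_pupil_samples = length(dl) + length(dr))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("interval_eye_metrics", "data.frame")
  out
}

#' Screen participants by capture rate
#'
#' Keeps participants whose tracker capture rate reaches `min_rate` and
#' reports the exclusions together with the threshold used.
#'
#' @param rates Named numeric vector of capture rates (names = participant
#'   IDs).
#' @param min_rate Inclusion threshold in `[0, 1]` (default 0.6).
#' @return Object of class `screening_report`: list with `included`
#'   (character IDs), `excluded` (data frame of id/rate) and `min_rate`.
#' @export
filter_participants <- function(rates, min_rate = 0.6) {
  if (min_rate < 0 || min_rate > 1) {
    stop_cogload("invalid-input", "min_rate must lie in [0, 1]")
  }
  keep <- rates >= min_rate
  structure(
    list(included = names(rates)[keep],
         excluded = data.frame(id = names(rates)[!keep],
                               rate = as.numeric(rates[!keep])),
         min_rate = min_rate),
    class = "screening_report")
}

#' @export
print.screening_report <- function(x, ...) {
  cat(sprintf("Capture-rate screening (threshold %.2f): %d included, %d excluded\n",
              x$min_rate, length(x$included), nrow(x$excluded)))
  if (nrow(x$excluded)) print.data.frame(x$excluded)
  invisible(x)
}

#' Participant-level astigmatism covariate
#'
#' The arithmetic mean of the two per-eye astigmatism degrees, used as a
#' covariate for tracker capture quality.
#'
#' @param left_deg,right_deg Nonnegative astigmatism degrees.
#' @return Numeric mean degree (vectorised).
#' @export
astigmatism_covariate <- function(left_deg, right_deg) {
  if (any(left_deg < 0) || any(right_deg < 0)) {
    stop_cogload("invalid-input", "astigmatism degrees must be >= 0")
  }
  (left_deg + right_deg) / 2
}
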
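#' Multichannel EEG recording container
#'
#' A uniform-rate, four-channel raw EEG segment with an absolute (Unix
#' seconds) start time. Channel names default to the dry-electrode montage
#' TP9, AF7, AF8, TP10.
#'
#' @param data Numeric matrix, samples x channels, microvolts; column names
#'   are the channel labels.
#' @param sampling_rate Sampling rate, Hz.
#' @param start_ts Unix time (seconds) of the first sample.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, sampling_rate, start_ts) {
  data <- as.matrix(data)
  if (is.null(colnames(data))) {
    stop_cogload("invalid-input", "EEG data must have channel column names")
  }
  if (!is.numeric(sampling_rate) || sampling_rate <= 0) {
    stop_cogload("invalid-input", "sampling_rate must be > 0")
  }
  structure(list(data = data, sampling_rate = as.numeric(sampling_rate),
                 start_ts = as.numeric(start_ts)),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("EEG recording: %d samples x %d channels (%s) @ %g Hz, %.1f s\n",
              nrow(x$data), ncol(x$data),
              paste(colnames(x$data), collapse = ", "),
              x$sampling_rate, nrow(x$data) / x$sampling_rate))
  invisible(x)
}

# Sample timestamps of a recording (or power series), Unix seconds.
rec_times <- function(x) {
  n <- nrow(x$data %||% x$power)
  x$start_ts + (seq_len(n) - 1L) / x$sampling_rate
}

#' Frequency-band definitions
#'
#' Default band edges for the three workload-relevant rhythms: Theta 4--8 Hz,
#' Alpha 8--13 Hz, Beta 13--30 Hz. All edges are configurable.
#'
#' @param Theta,Alpha,Beta Length-2 numeric `c(lo, hi)` in Hz.
#' @return Named list of band edge vectors.
#' @export
band_defs <- function(Theta = c(4, 8), Alpha = c(8, 13), Beta = c(13, 30)) {
  bands <- list(Theta = Theta, Alpha = Alpha, Beta = Beta)
  for (nm in names(bands)) {
    b <- bands[[nm]]
    if (length(b) != 2L || b[1] <= 0 || b[1] >= b[2]) {
      stop_cogload("configuration",
                   sprintf("band %s must satisfy 0 < lo < hi", nm))
    }
  }
  bands
}

#' Zero-phase Butterworth band-pass filter
#'
#' Filters every channel with a Butterworth band-pass applied
#' forward-backward (`signal::filtfilt`), so the output is zero-phase and
#' keeps its timestamps. The effective attenuation one octave outside the
#' band exceeds 20 dB at the default order.
#'
#' @param recording An [eeg_recording()].
#' @param band Length-2 numeric `c(lo, hi)` in Hz; both edges must lie below
#'   the Nyquist frequency.
#' @param order Butterworth prototype order (per edge) before the band-pass
#'   transformation.
#' @return A filtered `eeg_recording`.
#' @export
bandpass <- function(recording, band, order = 4L) {
  fs <- recording$sampling_rate
  if (length(band) != 2L || band[1] <= 0 || band[1] >= band[2] ||
      band[2] >= fs / 2) {
    stop_cogload("configuration",
                 "band edges must satisfy 0 < lo < hi < sampling_rate/2")
  }
  bf <- signal::butter(order, band / (fs / 2), type = "pass")
  out <- recording
  out$data <- apply(recording$data, 2L, function(x) {
    if (length(x) == 0L) return(x)
    as.numeric(signal::filtfilt(bf, x))
  })
  if (!is.matrix(out$data)) {
    out$data <- matrix(out$data, ncol = ncol(recording$data),
                       dimnames = dimnames(recording$data))
  }
  colnames(out$data) <- colnames(recording$data)
  attr(out, "band") <- band
  out
}

#' Zero-phase notch filter for mains interference
#'
#' Removes 50 Hz or 60 Hz power-line noise with a Butterworth band-stop
#' applied forward-backward.
#'
#' @param recording An [eeg_recording()].
#' @param freq Line frequency, Hz (50 or 60 typically).
#' @param width Half-width of the stop band, Hz.
#' @param order Butterworth prototype order.
#' @return A filtered `eeg_recording`.
#' @export
notch_filter <- function(recording, freq = 50, width = 2, order = 2L) {
  fs <- recording$sampling_rate
  if (freq + width >= fs / 2 || freq - width <= 0) {
    stop_cogload("configuration", "notch band must lie inside (0, Nyquist)")
  }
  bf <- signal::butter(order, c(freq - width, freq + width) / (fs / 2),
                       type = "stop")
  out <- recording
  out$data <- apply(recording$data, 2L,
                    function(x) as.numeric(signal::filtfilt(bf, x)))
  colnames(out$data) <- colnames(recording$data)
  out
}

#' Instantaneous power samples
#'
#' Squares the (band-filtered) amplitude samples elementwise, giving
#' instantaneous power in microvolts squared.
#'
#' @param recording An [eeg_recording()] (typically band-filtered).
#' @return An object of class `power_series` with elements `power`
#'   (samples x channels matrix), `sampling_rate` and `start_ts`.
#' @export
power_samples <- function(recording) {
  structure(list(power = recording$data^2,
                 sampling_rate = recording$sampling_rate,
                 start_ts = recording$start_ts),
            class = "power_series")
}

#' Mean power of one channel over a time interval
#'
#' Arithmetic mean of the power samples whose timestamps fall in the
#' half-open interval `[start, end)`. The number of samples used is attached
#' as attribute `n_samples`.
#'
#' @param power A `power_series` from [power_samples()].
#' @param interval Length-2 numeric `c(start, end)`, Unix seconds.
#' @param channel Channel name (column of the power matrix).
#' @return Scalar mean power, microvolts squared.
#' @export
mean_power <- function(power, interval, channel) {
  if (!channel %in% colnames(power$power)) {
    stop_cogload("invalid-input", sprintf("unknown channel '%s'", channel))
  }
  idx <- in_interval(rec_times(power), interval[1], interval[2])
  if (length(idx) == 0L) {
    stop_cogload("insufficient-data",
                 sprintf("no samples in [%.3f, %.3f)", interval[1], interval[2]))
  }
  structure(mean(power$power[idx, channel]), n_samples = length(idx))
}

#' Event-locked analysis intervals of a task log
#'
#' Builds, per trial, the activation interval (letter onset to the response,
#' or the full `stimulus_timeout` when the trial timed out, flagged) and the
#' near baseline (the `near_width` seconds immediately before onset), plus a
#' single away baseline covering the first `away_length` seconds of the
#' eyes-open rest. All intervals are half-open `[start, end)`.
#'
#' @param task_log Data frame with columns `start_unix`, `end_unix`,
#'   `choice`, `n_back` (1 or 2), ordered by onset.
#' @param rest_start Unix time at which the eyes-open rest begins.
#' @param stimulus_timeout Stimulus timeout, seconds.
#' @param near_width Near-baseline window length, seconds (default 0.200 s).
#' @param away_length Away-baseline segment length, seconds (default 3 s).
#' @return Data frame of intervals with columns `kind`
#'   (`activation`/`baseline_near`/`baseline_away`), `start`, `end`,
#'   `trial_index`, `condition` and `timeout` flag.
#' @export
segment_trials <- function(task_log, rest_start, stimulus_timeout = 3,
                           near_width = 0.2, away_length = 3) {
  onset <- as.numeric(task_log$start_unix)
  if (is.unsorted(onset, strictly = TRUE)) {
    stop_cogload("data-integrity", "letter onsets must be strictly increasing")
  }
  resp <- as.numeric(task_log$end_unix)
  timeout <- task_log$choice == "none" | is.na(resp)
  act_end <- ifelse(timeout, onset + stimulus_timeout, resp)
  if (any(!timeout & (resp <= onset))) {
    stop_cogload("data-integrity", "response recorded before letter onset")
  }
  if (any(!timeout & (resp - onset > stimulus_timeout + 1e-9))) {
    stop_cogload("data-integrity",
                 "activation interval exceeds the stimulus timeout")
  }
  n <- length(onset)
  cond <- as.integer(task_log$n_back)
  rbind(
    data.frame(kind = "activation", start = onset, end = act_end,
               trial_index = seq_len(n), condition = cond, timeout = timeout),
    data.frame(kind = "baseline_near", start = onset - near_width, end = onset,
               trial_index = seq_len(n), condition = cond, timeout = timeout),
    data.frame(kind = "baseline_away", start = rest_start,
               end = rest_start + away_length, trial_index = NA_integer_,
               condition = NA_integer_, timeout = FALSE))
}

#' Event-related desynchronization / synchronization
#'
#' The band-power change of an activation interval relative to its reference
#' interval: `value_fraction = (R - A) / R`, and `value_percent` is that
#' fraction times 100. Positive values mean the band power dropped below the
#' baseline; negative values mean it rose. (In the workload literature the
#' same quantity is read with either sign labelled as ERD or ERS; this
#' function only evaluates the formula and carries the reading as
#' `sign_note`.)
#'
#' @param R Mean reference (baseline) power, must be > 0.
#' @param A Mean activation power, must be >= 0. Vectors recycle as usual.
#' @return Object of class `erd_result` with `value_fraction`,
#'   `value_percent` and `sign_note`.
#' @examples
#' erd(2, 1)$value_percent   # 50
#' erd(1, 0)$value_percent   # 100
#' erd(1, 2)$value_percent   # -100
#' @export
erd <- function(R, A) {
  if (any(!is.finite(R)) || any(R <= 0)) {
    stop_cogload("undefined-baseline", "reference power R must be finite and > 0")
  }
  if (any(!is.finite(A)) || any(A < 0)) {
    stop_cogload("invalid-input", "activation power A must be finite and >= 0")
  }
  vf <- (R - A) / R
  structure(
    list(value_fraction = vf, value_percent = 100 * vf,
         sign_note = paste("negative values indicate a power increase over",
                           "the baseline; positive values a power decrease")),
    class = "erd_result")
}

#' @export
print.erd_result <- function(x, ...) {
  cat("ERD/ERS, (R - A) / R:\n")
  print(data.frame(fraction = x$value_fraction, percent = x$value_percent))
  cat("note:", x$sign_note, "\n")
  invisible(x)
}

#' Per-trial, per-channel, per-band ERD/ERS table
#'
#' Runs the full event-locked quantification on one recording: optional
#' notch filtering, zero-phase band-pass per band, squaring to power,
#' averaging power over each trial's activation interval (A) and over the
#' reference interval (R), then `(R - A)/R`. With `baseline = "near"` each
#' trial uses its own 200 ms pre-onset window; with `baseline = "away"` all
#' trials share the single 3 s segment at the start of the eyes-open rest.
#'
#' Trials whose intervals contain no samples (or a non-positive reference
#' power) are excluded and counted; interval edges falling outside the
#' recording are clipped and flagged.
#'
#' @param recording An [eeg_recording()] covering the task span.
#' @param task_log Task log data frame (see [segment_trials()]).
#' @param rest_start Unix time of the eyes-open rest onset.
#' @param bands Named list of band edges, as from [band_defs()].
#' @param channels Channel names to process (default: all columns).
#' @param baseline `"near"` or `"away"`.
#' @param notch Optional mains frequency (50 or 60) to notch out first.
#' @param stimulus_timeout,near_width,away_length Passed to
#'   [segment_trials()].
#' @return Data frame of class `erd_table` with one row per
#'   (trial, channel, band): `trial_index`, `condition`, `channel`, `band`,
#'   `R`, `A`, `value_fraction`, `value_percent`, `clipped`, `timeout`.
#'   Attributes: `baseline`, `excluded` (data frame of excluded
#'   trial/channel/band rows with reasons), `n_trials`.
#' @export
erd_table <- function(recording, task_log, rest_start, bands = band_defs(),
                      channels = NULL, baseline = c("near", "away"),
                      notch = NULL, stimulus_timeout = 3, near_width = 0.2,
                      away_length = 3) {
  baseline <- match.arg(baseline)
  channels <- channels %||% colnames(recording$data)
  iv <- segment_trials(task_log, rest_start, stimulus_timeout,
                       near_width, away_length)
  span <- c(recording$start_ts,
            recording$start_ts + nrow(recording$data) / recording$sampling_rate)
  if (!is.null(notch)) recording <- notch_filter(recording, freq = notch)

  act <- iv[iv$kind == "activation", ]
  near <- iv[iv$kind == "baseline_near", ]
  away <- iv[iv$kind == "baseline_away", ][1L, ]

  rows <- list(); excl <- list()
  for (bname in names(bands)) {
    ps <- power_samples(bandpass(recording, bands[[bname]]))
    ts <- rec_times(ps)
    for (ch in channels) {
      away_R <- NULL
      if (baseline == "away") {
        idx <- in_interval(ts, away$start, away$end)
        if (length(idx) == 0L) {
          stop_cogload("insufficient-data",
                       "away baseline lies outside the recording")
        }
        away_R <- mean(ps$power[idx, ch])
      }
      for (i in seq_len(nrow(act))) {
        a_int <- c(max(act$start[i], span[1]), min(act$end[i], span[2]))
        clipped <- a_int[1] > act$start[i] || a_int[2] < act$end[i]
        ai <- in_interval(ts, a_int[1], a_int[2])
        if (length(ai) == 0L) {
          excl[[length(excl) + 1L]] <- data.frame(
            trial_index = act$trial_index[i], channel = ch, band = bname,
            reason = "no activation samples")
          next
        }
        A <- mean(ps$power[ai, ch])
        if (baseline == "near") {
          b_int <- c(max(near$start[i], span[1]), min(near$end[i], span[2]))
          clipped <- clipped || b_int[1] > near$start[i]
          ri <- in_interval(ts, b_int[1], b_int[2])
          if (length(ri) == 0L) {
            excl[[length(excl) + 1L]] <- data.frame(
              trial_index = act$trial_index[i], channel = ch, band = bname,
              reason = "no baseline samples")
            next
          }
          R <- mean(ps$power[ri, ch])
        } else {
          R <- away_R
        }
        if (!is.finite(R) || R <= 0) {
          excl[[length(excl) + 1L]] <- data.frame(
            trial_index = act$trial_index[i], channel = ch, band = bname,
            reason = "non-positive reference power")
          next
        }
        vf <- (R - A) / R
        rows[[length(rows) + 1L]] <- data.frame(
          trial_index = act$trial_index[i], condition = act$condition[i],
          channel = ch, band = bname, R = R, A = A, value_fraction = vf,
          value_percent = 100 * vf, clipped = clipped,
          timeout = act$timeout[i])
      }
    }
  }
  if (length(rows) == 0L) {
    stop_cogload("empty-result", "no trial produced a valid ERD value")
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "baseline") <- baseline
  attr(out, "excluded") <- if (length(excl)) do.call(rbind, excl) else
    data.frame(trial_index = integer(), channel = character(),
               band = character(), reason = character())
  attr(out, "n_trials") <- nrow(act)
  class(out) <- c("erd_table", "data.frame")
  out
}

#' Condition-level summary of an ERD table
#'
#' @param object An `erd_table`.
#' @param ... Unused.
#' @return Data frame with per (band, channel, condition) trial counts and
#'   mean/median `value_fraction`.
#' @export
summary.erd_table <- function(object, ...) {
  sp <- split(object,
              list(object$band, object$channel, object$condition), drop = TRUE)
  out <- do.call(rbind, lapply(sp, function(d) {
    data.frame(band = d$band[1], channel = d$channel[1],
               condition = d$condition[1], n = nrow(d),
               mean_fraction = mean(d$value_fraction),
               median_fraction = stats::median(d$value_fraction))
  }))
  rownames(out) <- NULL
  out[order(out$band, out$channel, out$condition), ]
}

#' @export
print.erd_table <- function(x, ...) {
  cat(sprintf("ERD/ERS table (%s baseline): %d rows, %d trials, %d excluded\n",
              attr(x, "baseline"), nrow(x), attr(x, "n_trials"),
              nrow(attr(x, "excluded"))))
  print.data.frame(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}
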
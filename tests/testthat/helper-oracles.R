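# Independent brute-force oracles used to check the statistical routines.
# These deliberately avoid the code paths of the package implementation
# (which uses pwilcox / the normal approximation / the t approximation).

# Null distribution of the rank-sum W of sample 1 (sizes n1, n2, no ties),
# by exhaustive enumeration of all C(N, n1) rank assignments.
oracle_ranksum_dist <- function(n1, n2) {
  N <- n1 + n2
  sets <- utils::combn(N, n1)
  ws <- colSums(matrix(seq_len(N)[sets], nrow = n1))
  table(ws) / ncol(sets)
}

# Exhaustive two-sided p-value for observed rank sum w.
oracle_ranksum_p <- function(w, dist) {
  vals <- as.numeric(names(dist))
  lo <- sum(dist[vals <= w])
  hi <- sum(dist[vals >= w])
  min(1, 2 * min(lo, hi))
}

# Build a power series with explicit values and timing (for mean_power).
make_power_series <- function(values, fs = 10, start_ts = 0,
                              channel = "AF7") {
  rec <- eeg_recording(matrix(sqrt(values), ncol = 1,
                              dimnames = list(NULL, channel)),
                       fs, start_ts)
  power_samples(rec)
}

# Minimal synthetic gaze stream: constant pupil, optional validity pattern.
make_gaze <- function(ts, x = 0, y = 0, pupil = 3, valid = TRUE,
                      events = NULL) {
  n <- length(ts)
  gaze_stream(data.frame(ts = ts,
                         x = rep_len(x, n), y = rep_len(y, n),
                         pupil_left = rep_len(pupil, n),
                         pupil_right = rep_len(pupil, n),
                         valid_left = rep_len(valid, n),
                         valid_right = rep_len(valid, n)),
              events = events, sampling_rate = 1 / stats::median(diff(ts)))
}

# Task-log rows with chosen onsets/responses (choice defaults to match).
make_log <- function(onsets, responses, n_back = 1L,
                     choice = NULL, id = 101L) {
  choice <- choice %||% ifelse(is.na(responses), "none", "match")
  data.frame(id = id, n_back = n_back,
             letter = rep_len(LETTERS[1:4], length(onsets)),
             choice = choice,
             accuracy = ifelse(is.na(responses), "no", "yes"),
             reaction_time = responses - onsets,
             start_unix = onsets,
             end_unix = ifelse(is.na(responses), onsets + 3, responses))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
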
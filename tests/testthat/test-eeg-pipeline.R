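sine_recording <- function(freq, amp = 1, fs = 256, secs = 8,
                           channels = c("TP9", "AF7", "AF8", "TP10")) {
  t <- seq(0, secs - 1 / fs, by = 1 / fs)
  x <- amp * sin(2 * pi * freq * t)
  eeg_recording(matrix(x, ncol = length(channels), nrow = length(t),
                       dimnames = list(NULL, channels)),
                fs, start_ts = 0)
}

rms_mid <- function(rec, ch = "AF7") {
  n <- nrow(rec$data)
  mid <- seq(floor(n / 4), floor(3 * n / 4))  # avoid filter edge transients
  sqrt(mean(rec$data[mid, ch]^2))
}

test_that("band-pass keeps in-band sinusoids and rejects out-of-band ones", {
  rec <- sine_recording(10, amp = 2)
  in_alpha <- bandpass(rec, c(8, 13))
  expect_equal(rms_mid(in_alpha), 2 / sqrt(2), tolerance = 0.05)
  in_beta <- bandpass(rec, c(13, 30))
  expect_lt(rms_mid(in_beta), rms_mid(in_alpha) / 10)

  zero <- rec; zero$data[] <- 0
  expect_equal(max(abs(bandpass(zero, c(8, 13))$data)), 0)
})

test_that("band edges beyond Nyquist are a configuration error", {
  rec <- sine_recording(10, fs = 64)
  expect_error(bandpass(rec, c(13, 40)), "configuration")
  expect_error(band_defs(Alpha = c(13, 8)), "configuration")
})

test_that("notch filtering removes a mains component", {
  t <- seq(0, 8 - 1 / 256, by = 1 / 256)
  x <- sin(2 * pi * 10 * t) + 2 * sin(2 * pi * 50 * t)
  rec <- eeg_recording(matrix(x, ncol = 1, dimnames = list(NULL, "AF7")),
                       256, 0)
  cleaned <- notch_filter(rec, 50)
  # 10 Hz carrier survives, the 50 Hz component collapses
  expect_equal(rms_mid(bandpass(cleaned, c(8, 13))), 1 / sqrt(2),
               tolerance = 0.05)
  expect_lt(rms_mid(bandpass(cleaned, c(45, 55))), 0.1)
})

test_that("power samples are squared amplitudes", {
  rec <- sine_recording(10, amp = 3)
  rec$data[] <- 2
  expect_true(all(power_samples(rec)$power == 4))

  sine <- sine_recording(10, amp = 3)
  expect_equal(mean(power_samples(sine)$power[, "AF7"]), 9 / 2,
               tolerance = 1e-3)

  empty <- eeg_recording(matrix(numeric(0), ncol = 1,
                                dimnames = list(NULL, "AF7")), 256, 0)
  expect_identical(nrow(power_samples(empty)$power), 0L)
})

test_that("mean power averages samples inside the half-open interval", {
  ps <- make_power_series(rep(4, 50), fs = 10, start_ts = 0)
  expect_equal(as.numeric(mean_power(ps, c(1, 3), "AF7")), 4)

  two <- make_power_series(c(2, 6), fs = 10, start_ts = 0)
  mp <- mean_power(two, c(0, 1), "AF7")
  expect_equal(as.numeric(mp), 4)
  expect_identical(attr(mp, "n_samples"), 2L)

  expect_error(mean_power(ps, c(100, 101), "AF7"), "insufficient-data")
  expect_error(mean_power(ps, c(1, 3), "XX"), "invalid-input")
})

test_that("segmentation yields one activation + near baseline per trial and one away baseline", {
  onsets <- seq(100, by = 3, length.out = 20)
  log <- make_log(onsets, onsets + 1.2)
  iv <- segment_trials(log, rest_start = 80)
  expect_identical(sum(iv$kind == "activation"), 20L)
  expect_identical(sum(iv$kind == "baseline_near"), 20L)
  expect_identical(sum(iv$kind == "baseline_away"), 1L)
  near <- iv[iv$kind == "baseline_near", ]
  expect_true(all(abs((near$end - near$start) - 0.2) < 1e-12))
  away <- iv[iv$kind == "baseline_away", ]
  expect_equal(away$end - away$start, 3)
  expect_equal(away$start, 80)
})

test_that("unanswered trials get a full-length activation window, flagged", {
  log <- make_log(c(0, 5), c(1.1, NA))
  iv <- segment_trials(log, rest_start = -20)
  act <- iv[iv$kind == "activation", ]
  expect_equal(act$end[2] - act$start[2], 3)
  expect_true(act$timeout[2])
  expect_false(act$timeout[1])
})

test_that("segmentation rejects inconsistent timing", {
  log <- make_log(c(0, 5), c(1, 5.5))
  log$start_unix <- c(5, 0)
  expect_error(segment_trials(log, 0), "increasing")
  log2 <- make_log(c(0, 5), c(1, 4.5))  # response before onset
  expect_error(segment_trials(log2, -10), "data-integrity")
})

test_that("the ERD/ERS formula satisfies its algebraic identities", {
  expect_equal(erd(2, 1)$value_fraction, 0.5)
  expect_equal(erd(2, 1)$value_percent, 50)
  expect_equal(erd(7, 7)$value_percent, 0)
  expect_equal(erd(1, 0)$value_percent, 100)
  expect_equal(erd(1, 2)$value_percent, -100)
  expect_error(erd(0, 1), "undefined-baseline")
  expect_error(erd(-1, 1), "undefined-baseline")
  expect_error(erd(1, -1), "invalid-input")

  # scale invariance and monotonicity in A, over a grid
  for (R in c(0.5, 1, 3)) {
    A <- seq(0, 2 * R, length.out = 9)
    v <- erd(rep(R, 9), A)$value_fraction
    expect_true(all(diff(v) < 0))
    expect_true(all(v <= 1))
    for (c_scale in c(0.1, 2, 1000)) {
      expect_equal(erd(c_scale * R, c_scale * A)$value_fraction, v)
    }
  }
})

test_that("the ERD table accounts for every trial per channel and band", {
  set.seed(42)
  b <- simulate_session(103, eeg = eeg_sim_config(noise_amplitude = 1),
                        gaze = NULL, seed = 42)
  et <- erd_table(b$eeg, b$task_log, b$rest_interval[1])
  n_trials <- attr(et, "n_trials")
  expect_identical(n_trials, nrow(b$task_log))
  counts <- table(et$channel, et$band)
  excl <- attr(et, "excluded")
  for (ch in rownames(counts)) {
    for (bd in colnames(counts)) {
      n_excl <- sum(excl$channel == ch & excl$band == bd)
      expect_identical(as.integer(counts[ch, bd] + n_excl), n_trials)
    }
  }
  expect_true(all(et$R > 0))
  expect_true(all(et$A >= 0))
  expect_equal(et$value_percent, 100 * et$value_fraction)
})

test_that("near and away baselines agree on the sign of the condition difference", {
  truth <- erd_truth_default()
  truth$d <- 0
  truth$d[truth$band == "Alpha" & truth$channel == "AF7"] <- c(-0.1, -0.3)
  cfg <- eeg_sim_config(erd_truth = truth, noise_amplitude = 0.5)
  b <- simulate_session(105, eeg = cfg, gaze = NULL, seed = 19)
  diff_of <- function(mode) {
    et <- erd_table(b$eeg, b$task_log, b$rest_interval[1],
                    bands = list(Alpha = c(8, 13)), channels = "AF7",
                    baseline = mode)
    mean(et$value_fraction[et$condition == 2]) -
      mean(et$value_fraction[et$condition == 1])
  }
  expect_identical(sign(diff_of("near")), sign(diff_of("away")))
})
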
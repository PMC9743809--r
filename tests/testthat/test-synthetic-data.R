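test_that("band-power injection scales mean power by exactly (1 - d)", {
  # single pure oscillation, no background noise: raw squared samples inside
  # an activation window must average (1 - d) times the rest-window power
  d <- 0.4
  truth <- erd_truth_default()
  truth$d <- 0
  truth$d[truth$band == "Alpha" & truth$condition == 2] <- d
  cfg <- eeg_sim_config(band_amplitudes = c(Theta = 0, Alpha = 20, Beta = 0),
                        erd_truth = truth, noise_amplitude = 1e-12)
  b <- simulate_session(101, eeg = cfg, gaze = NULL, seed = 14)
  ps <- power_samples(b$eeg)  # no filtering: the injection itself is tested
  iv <- segment_trials(b$task_log, b$rest_interval[1])
  act <- iv[iv$kind == "activation" & iv$condition == 2, ]
  R <- as.numeric(mean_power(ps, b$rest_interval, "AF7"))
  ratios <- vapply(seq_len(nrow(act)), function(i) {
    as.numeric(mean_power(ps, c(act$start[i], act$end[i]), "AF7")) / R
  }, numeric(1))
  # per-trial cycle truncation averages out across trials
  expect_equal(mean(ratios), 1 - d, tolerance = 0.01)
})

test_that("null effects produce near-zero mean ERD", {
  truth <- erd_truth_default()
  truth$d <- 0
  cfg <- eeg_sim_config(erd_truth = truth, noise_amplitude = 0.5)
  b <- simulate_session(101, eeg = cfg, gaze = NULL, seed = 33)
  et <- erd_table(b$eeg, b$task_log, b$rest_interval[1],
                  bands = list(Alpha = c(8, 13)), channels = "AF7")
  for (cond in 1:2) {
    v <- et$value_fraction[et$condition == cond]
    expect_lt(abs(mean(v)), 3 * stats::sd(v) / sqrt(length(v)) + 0.01)
  }
})

test_that("interval-dilation draws reproduce their configured summaries", {
  cfg <- gaze_sim_config()
  set.seed(10)
  for (cond in 1:2) {
    par <- cfg$pupil_interval[[paste0("cond", cond)]]
    x <- r_interval_dilation(2e5, cond, cfg)
    expect_equal(median(x), par$median, tolerance = 0.01)
    expect_equal(sd(x), par$sd, tolerance = 0.01)
  }
  # as fast noise vanishes the pipeline recovers the injected trial values
  quiet <- gaze_sim_config(pupil_noise_sd = 1e-6, missing_prob = 0)
  b <- simulate_session(101, eeg = NULL, gaze = quiet, seed = 6)
  bl <- pupil_baseline(b$gaze, b$rest_interval)
  iv <- segment_trials(b$task_log, b$rest_interval[1])
  act <- iv[iv$kind == "activation", ]
  m <- interval_metrics(b$gaze, act, bl)
  expect_equal(m$avg_pupil_dilation_left,
               b$ground_truth$trial_dilation, tolerance = 1e-3)
})

test_that("extreme missingness zeroes the capture rate", {
  cfg <- gaze_sim_config(missing_prob = 1)
  b <- simulate_session(101, eeg = NULL, gaze = cfg, seed = 2)
  expect_equal(as.numeric(capture_rate(b$gaze)), 0)
})

test_that("astigmatism-coupled missingness yields the target negative rank correlation", {
  d <- simulate_capture_astigmatism(4000, rho = -0.55, seed = 17)
  r <- spearman_cor(d$astigmatism, d$capture_rate)
  expect_lt(r$rho, 0)
  expect_equal(r$rho, -0.55, tolerance = 0.05)
  # monotone coupling: latent missingness rises with astigmatism rank
  expect_gt(spearman_cor(d$astigmatism, d$missing_prob)$rho, 0)
})

test_that("session bundles are reproducible from their seed", {
  a <- simulate_session(104, seed = 55)
  b <- simulate_session(104, seed = 55)
  expect_identical(a$task_log, b$task_log)
  expect_identical(a$eeg$data, b$eeg$data)
  expect_identical(a$gaze$samples, b$gaze$samples)
  c2 <- simulate_session(104, seed = 56)
  expect_false(identical(a$task_log, c2$task_log))
})

test_that("session timelines follow rest / block / rest / block with parity order", {
  b <- simulate_session(101, eeg = NULL, gaze = NULL, seed = 1)
  tl <- b$timeline
  expect_identical(tl$segment,
                   c("rest_eyes_open", "block1", "rest_between", "block2"))
  expect_equal(tl$end[1] - tl$start[1], 10)  # eyes-open rest
  expect_equal(tl$start[4] - tl$end[2], 5)   # inter-block rest
  expect_identical(tl$condition[2], 1L)      # odd ID: low block first
  b2 <- simulate_session(102, eeg = NULL, gaze = NULL, seed = 1)
  expect_identical(b2$timeline$condition[2], 2L)
  # trials sit inside their blocks and never overlap the rests
  log <- b$task_log
  expect_true(all(log$start_unix >= tl$start[2]))
  expect_true(all(log$end_unix[log$n_back == 1] <= tl$end[2]))
  expect_true(all(log$start_unix[log$n_back == 2] >= tl$start[4]))
})

test_that("cohorts counterbalance, honour dropout, and reproduce under a seed", {
  co <- simulate_cohort(4, ids = 101:104, dropout = integer(0),
                        eeg = NULL, gaze = NULL, seed = 3)
  expect_identical(sum(co$truth$order == "Order1"), 2L)
  expect_identical(sum(co$truth$order == "Order2"), 2L)

  co2 <- simulate_cohort(4, ids = 101:104, dropout = integer(0),
                         eeg = NULL, gaze = NULL, seed = 3)
  expect_identical(co$bundles[["103"]]$task_log,
                   co2$bundles[["103"]]$task_log)
})

test_that("a 30-person cohort with the standard dropout has 29 analyzable records", {
  co <- simulate_cohort(30, eeg = NULL, gaze = NULL, seed = 12)
  expect_identical(sum(co$truth$dropout), 1L)
  expect_true(co$bundles[["126"]]$dropout)
  expect_null(co$bundles[["126"]]$task_log)
  analyzable <- Filter(function(b) !b$dropout, co$bundles)
  expect_identical(length(analyzable), 29L)
})

test_that("1/f noise has a decaying spectrum and the requested scale", {
  set.seed(20)
  x <- pink_noise(2^14, exponent = 1, sd = 2)
  expect_equal(sd(x), 2, tolerance = 1e-6)
  sp <- abs(fft(x))[2:2^13]^2
  f <- seq_along(sp)
  slope <- coef(lm(log(sp) ~ log(f)))[2]
  expect_equal(unname(slope), -1, tolerance = 0.15)
})
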
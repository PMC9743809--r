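test_that("a stationary gaze becomes a single fixation of the right length", {
  ts <- seq(0, 1, by = 1 / 60)
  st <- make_gaze(ts, x = 100, y = 100)
  ev <- ivt_detect(st, px_per_deg = 35)
  expect_identical(nrow(ev), 1L)
  expect_identical(ev$kind, "fixation")
  expect_equal(ev$duration_ms, 1000, tolerance = 0.05)
})

test_that("a fast jump between two dwell points is fixation-saccade-fixation", {
  fs <- 60
  ts <- seq(0, 2, by = 1 / fs)
  x <- ifelse(ts < 1, 0, 700)  # 20 deg jump at 35 px/deg in one sample
  st <- make_gaze(ts, x = 0)
  st$samples$x <- x
  ev <- ivt_detect(st, px_per_deg = 35)
  expect_identical(ev$kind, c("fixation", "saccade", "fixation"))
})

test_that("invalid streams and missing geometry are handled explicitly", {
  ts <- seq(0, 1, by = 1 / 60)
  st <- make_gaze(ts, valid = FALSE)
  st$samples$pupil_left <- NA_real_
  st$samples$pupil_right <- NA_real_
  expect_identical(nrow(ivt_detect(st, px_per_deg = 35)), 0L)
  expect_error(ivt_detect(make_gaze(ts), px_per_deg = NULL), "configuration")
})

test_that("capture rate is the valid-sample fraction", {
  ts <- seq(0, 1, by = 0.01)
  expect_equal(as.numeric(capture_rate(make_gaze(ts))), 1.0)
  st <- make_gaze(ts)
  half <- seq_len(nrow(st$samples)) %% 2 == 0
  st$samples$valid_left[half] <- FALSE
  st$samples$pupil_left[half] <- NA
  expect_equal(as.numeric(capture_rate(st, policy = "both")),
               mean(!half))
  expect_equal(as.numeric(capture_rate(st, policy = "right")), 1.0)
  empty <- make_gaze(numeric(0))
  expect_error(capture_rate(empty), "insufficient-data")
})

test_that("generated streams realise their configured missingness", {
  cfg <- gaze_sim_config(missing_prob = 0.3)
  b <- simulate_session(101, eeg = NULL, gaze = cfg, seed = 21)
  cr <- capture_rate(b$gaze)
  n <- attr(cr, "n_total")
  ci <- qbinom(c(0.0005, 0.9995), n, 0.7) / n
  expect_gte(as.numeric(cr), ci[1])
  expect_lte(as.numeric(cr), ci[2])
})

test_that("the pupil baseline is the mean valid rest diameter per eye", {
  ts <- seq(0, 10, by = 1 / 60)
  st <- make_gaze(ts, pupil = 3.0)
  bl <- pupil_baseline(st, c(0, 10))
  expect_equal(bl$left, 3.0)
  expect_equal(bl$right, 3.0)

  st2 <- make_gaze(ts, pupil = 3.0)
  st2$samples$pupil_left <- rep(c(2.9, 3.1), length.out = nrow(st2$samples))
  expect_equal(pupil_baseline(st2, c(0, 10))$left, 3.0)

  st3 <- make_gaze(ts, valid = FALSE)
  st3$samples$pupil_left <- NA_real_
  st3$samples$pupil_right <- NA_real_
  expect_error(pupil_baseline(st3, c(0, 10)), "insufficient-data")
})

test_that("interval metrics recover dilations and event rates by construction", {
  ts <- seq(0, 1 - 1 / 60, by = 1 / 60)
  st <- make_gaze(ts, pupil = 3.0)
  bl <- structure(list(left = 3.0, right = 3.0, window = c(-10, 0)),
                  class = "pupil_baseline")
  events <- data.frame(kind = rep("fixation", 3),
                       start_ts = c(0.1, 0.4, 0.7),
                       end_ts = c(0.3, 0.6, 0.9),
                       duration_ms = c(200, 200, 200))
  m <- interval_metrics(st, data.frame(start = 0, end = 1), bl,
                        events = events)
  expect_equal(m$avg_pupil_dilation_left, 0)
  expect_equal(m$max_pupil_dilation_left, 0)
  expect_equal(m$fixation_number_per_second, 3)
  expect_equal(m$avg_fixation_duration, 200)
  expect_true(is.na(m$avg_saccade_duration))  # flagged, not zero

  # two samples at baseline +/- 0.1: avg 0, max +0.1
  st2 <- make_gaze(c(0.0, 0.5), pupil = 3.0)
  st2$samples$pupil_left <- c(3.1, 2.9)
  st2$samples$pupil_right <- c(3.1, 2.9)
  m2 <- interval_metrics(st2, data.frame(start = 0, end = 1), bl,
                         events = events)
  expect_equal(m2$avg_pupil_dilation_left, 0)
  expect_equal(m2$max_pupil_dilation_left, 0.1)
})

test_that("dilation metrics are invariant to a common diameter shift", {
  set.seed(7)
  ts <- seq(0, 2, by = 1 / 60)
  st <- make_gaze(ts, pupil = 3.0)
  st$samples$pupil_left <- 3 + rnorm(length(ts), 0, 0.1)
  st$samples$pupil_right <- 3 + rnorm(length(ts), 0, 0.1)
  events <- data.frame(kind = "fixation", start_ts = 0.5, end_ts = 1,
                       duration_ms = 500)
  bl <- structure(list(left = 3, right = 3, window = c(-1, 0)),
                  class = "pupil_baseline")
  m0 <- interval_metrics(st, data.frame(start = 0, end = 2), bl, events)
  st$samples$pupil_left <- st$samples$pupil_left + 0.7
  st$samples$pupil_right <- st$samples$pupil_right + 0.7
  bl2 <- structure(list(left = 3.7, right = 3.7, window = c(-1, 0)),
                   class = "pupil_baseline")
  m1 <- interval_metrics(st, data.frame(start = 0, end = 2), bl2, events)
  expect_equal(m1$avg_pupil_dilation_left, m0$avg_pupil_dilation_left)
  expect_equal(m1$max_pupil_dilation_right, m0$max_pupil_dilation_right)
})

test_that("participant screening applies the threshold and reports exclusions", {
  rates <- c(`101` = 0.9, `102` = 0.1)
  rep1 <- filter_participants(rates, 0.6)
  expect_identical(rep1$included, "101")
  expect_identical(rep1$excluded$id, "102")
  expect_identical(filter_participants(rates, 0)$included, c("101", "102"))
  expect_error(filter_participants(rates, 1.5), "invalid-input")
})

test_that("the astigmatism covariate is the two-eye mean", {
  expect_equal(astigmatism_covariate(500, 600), 550)
  expect_equal(astigmatism_covariate(0, 0), 0)
  expect_equal(astigmatism_covariate(100, 300), 200)
  expect_error(astigmatism_covariate(-1, 0), "invalid-input")
})

test_that("the condition shift in interval dilations has the expected sign almost surely", {
  cfg <- gaze_sim_config()
  set.seed(11)
  signs <- replicate(100, {
    x <- r_interval_dilation(245, 1, cfg)
    y <- r_interval_dilation(245, 2, cfg)
    sign(median(y) - median(x))
  })
  expect_gte(mean(signs > 0), 0.95)
})
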
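# Synthetic sessions (behaviour + EEG + gaze) with recorded ground truth.
# Defaults are calibrated to the summary statistics of the modelled study
# (reaction-time and accuracy summaries, condition-wise band-power changes,
# pupil-dilation medians and spread, fixation/saccade duration summaries,
# an astigmatism/capture-rate rank correlation of -0.55), so a simulated
# cohort reproduces the study conditions at the population level.

#' 1/f ("pink") background noise
#'
#' Spectrally shaped Gaussian noise: the Fourier magnitudes of white noise
#' are scaled by `f^(-exponent/2)` (power ~ `1/f^exponent`), the DC
#' component removed, and the series rescaled to the requested SD.
#'
#' @param n Number of samples.
#' @param exponent Spectral slope of the power spectrum (1 = pink).
#' @param sd Target standard deviation (microvolts for EEG use).
#' @return Numeric vector of length `n`.
#' @export
pink_noise <- function(n, exponent = 1, sd = 1) {
  if (n < 4L) return(stats::rnorm(n, 0, sd))
  X <- stats::fft(stats::rnorm(n))
  k <- 0:(n - 1)
  fsym <- pmin(k, n - k)
  sc <- c(0, fsym[-1]^(-exponent / 2))
  x <- Re(stats::fft(X * sc, inverse = TRUE)) / n
  sd * x / stats::sd(x)
}

# Lognormal parameters matched to a reported (median, mean) pair.
rt_lognormal_params <- function(median, mean) {
  if (mean <= median) stop_cogload("invalid-input", "need mean > median")
  list(meanlog = log(median), sdlog = sqrt(2 * (log(mean) - log(median))))
}

# Three-parameter (shifted, possibly mirrored, lognormal) family matched to
# a reported median / mean / SD triple; reduces to a normal when the
# reported mean and median coincide. Used for interval-level pupil effects.
shifted_lognormal_params <- function(median, mean, sd) {
  g <- mean - median
  if (abs(g) < 1e-10) {
    return(list(family = "normal", median = median, sd = sd))
  }
  s <- sign(g); g <- abs(g)
  ratio2 <- (sd / g)^2
  # w = exp(sigma^2/2) solves w^2 (w + 1)/(w - 1) = (sd/g)^2; the function
  # is decreasing on (1, phi) with phi the golden ratio, so the light-tail
  # root lives there whenever sd is large relative to the mean-median gap.
  phi <- (1 + sqrt(5)) / 2
  f <- function(w) w^2 * (w + 1) / (w - 1) - ratio2
  if (f(phi) > 0) {
    stop_cogload("invalid-input",
                 "median/mean/sd triple too skewed for this family")
  }
  w <- stats::uniroot(f, c(1 + 1e-12, phi), tol = 1e-14)$root
  sigma <- sqrt(2 * log(w))
  mu <- log(g / (w - 1))
  list(family = "shifted_lognormal", shift = median - s * exp(mu),
       mu = mu, sigma = sigma, sign = s, median = median, sd = sd)
}

r_shifted_lognormal <- function(n, par) {
  if (par$family == "normal") {
    stats::rnorm(n, par$median, par$sd)
  } else {
    par$shift + par$sign * stats::rlnorm(n, par$mu, par$sigma)
  }
}

#' Default injected band-power changes
#'
#' Per (band, channel, condition) fractional band-power change `d` injected
#' during activation intervals, on the `(R - A)/R` scale recovered by the
#' EEG pipeline. Defaults are the condition-wise median values the modelled
#' study reports for the near baseline: Theta rises in ERS terms (positive
#' d, power decrease) and Alpha/Beta carry negative d (power increase under
#' load), strongest at the left-frontal and left-temporal sites.
#'
#' @return Data frame with columns `band`, `channel`, `condition` (1/2) and
#'   `d` (fraction, `d < 1`).
#' @export
erd_truth_default <- function() {
  ch <- c("TP9", "AF7", "AF8", "TP10")
  tab <- rbind(
    data.frame(band = "Theta", channel = ch, condition = 1L,
               d = c(0.1606055, 0.3261652, 0.4962916, 0.1055942)),
    data.frame(band = "Theta", channel = ch, condition = 2L,
               d = c(0.1961127, 0.3993164, 0.4979768, 0.1440152)),
    data.frame(band = "Alpha", channel = ch, condition = 1L,
               d = c(-0.0708803, -0.1177238, -0.1905496, -0.0741198)),
    data.frame(band = "Alpha", channel = ch, condition = 2L,
               d = c(-0.0994483, -0.1726443, -0.2087486, -0.0839877)),
    data.frame(band = "Beta", channel = ch, condition = 1L,
               d = c(-0.053213, -0.0801937, -0.0811931, -0.0740742)),
    data.frame(band = "Beta", channel = ch, condition = 2L,
               d = c(-0.0645524, -0.0829866, -0.1054581, -0.0797461)))
  rownames(tab) <- NULL
  tab
}

#' EEG simulation configuration
#'
#' Stationary band-limited oscillations over 1/f background noise, with the
#' oscillation amplitude scaled by `sqrt(1 - d)` inside each activation
#' interval so that the mean band POWER changes by the fraction `d`
#' (negative `d` = power increase, the direction observed for Alpha/Beta
#' under load). Sampling rate and montage follow the consumer headband this
#' models (256 Hz; TP9, AF7, AF8, TP10).
#'
#' @param sampling_rate Hz.
#' @param channels Channel labels.
#' @param band_amplitudes Rest oscillation amplitude per band, microvolts.
#' @param band_freqs Carrier frequency per band, Hz (inside the band edges).
#' @param erd_truth Data frame as from [erd_truth_default()].
#' @param noise_exponent 1/f spectral slope of the background.
#' @param noise_amplitude Background noise SD, microvolts.
#' @param line_noise `"none"`, `50` or `60` (Hz).
#' @param line_amplitude Mains component amplitude, microvolts.
#' @return Object of class `eeg_sim_config`.
#' @export
eeg_sim_config <- function(sampling_rate = 256,
                           channels = c("TP9", "AF7", "AF8", "TP10"),
                           band_amplitudes = c(Theta = 10, Alpha = 20, Beta = 5),
                           band_freqs = c(Theta = 6, Alpha = 10, Beta = 20),
                           erd_truth = erd_truth_default(),
                           noise_exponent = 1, noise_amplitude = 2,
                           line_noise = "none", line_amplitude = 2) {
  if (any(erd_truth$d >= 1)) {
    stop_cogload("invalid-input", "fractional power change d must be < 1")
  }
  if (sampling_rate <= 2 * max(band_freqs)) {
    stop_cogload("invalid-input",
                 "sampling_rate must exceed twice the highest band frequency")
  }
  structure(list(sampling_rate = sampling_rate, channels = channels,
                 band_amplitudes = band_amplitudes, band_freqs = band_freqs,
                 erd_truth = erd_truth, noise_exponent = noise_exponent,
                 noise_amplitude = noise_amplitude, line_noise = line_noise,
                 line_amplitude = line_amplitude),
            class = "eeg_sim_config")
}

#' Gaze/pupillometry simulation configuration
#'
#' Gaze streams alternate lognormal-duration fixations and saccades; the
#' pupil trace is a per-participant baseline plus a per-trial interval-level
#' workload component plus fast sample noise. The interval-level component
#' is drawn, per condition, from a three-parameter skewed family matched to
#' the modelled study's reported median/mean/SD of averaged pupil dilation
#' (medians 0.113 vs 0.197 mm, SD ~ 0.37-0.39 mm), so pipeline-recovered
#' interval dilations reproduce that scale. Samples are dropped i.i.d. at
#' `missing_prob` (both eyes jointly), emulating tracker capture loss.
#'
#' @param sampling_rate Hz (default 60).
#' @param fixation_duration Per-condition lognormal parameters for fixation
#'   durations in ms, as `list(cond1 =, cond2 =)` of
#'   `list(meanlog, sdlog)`.
#' @param saccade_duration Same structure for saccade durations, ms.
#' @param pupil_baseline Participant resting pupil diameter, mm.
#' @param pupil_interval Per-condition interval-level dilation distribution
#'   (see [shifted_lognormal_params()] source); defaults matched to the
#'   reported left-eye summaries.
#' @param pupil_noise_sd Fast per-sample pupil noise SD, mm.
#' @param missing_prob Per-sample probability that the tracker loses both
#'   eyes.
#' @param astigmatism Participant astigmatism degree (covariate only).
#' @param px_per_deg Screen geometry for velocity computations.
#' @param fixation_jitter_px Gaze jitter SD within fixations, pixels.
#' @return Object of class `gaze_sim_config`.
#' @export
gaze_sim_config <- function(sampling_rate = 60,
                            fixation_duration = list(
                              cond1 = rt_lognormal_params(166.7222, 224.4167),
                              cond2 = rt_lognormal_params(166.4935, 217.8477)),
                            saccade_duration = list(
                              cond1 = rt_lognormal_params(25, 27.14384),
                              cond2 = rt_lognormal_params(25, 27.43823)),
                            pupil_baseline = 3.5,
                            pupil_interval = list(
                              cond1 = shifted_lognormal_params(
                                0.1129762, 0.0776042, 0.3685327),
                              cond2 = shifted_lognormal_params(
                                0.1967991, 0.2135481, 0.3894946)),
                            pupil_noise_sd = 0.05,
                            missing_prob = 0.1,
                            astigmatism = 0,
                            px_per_deg = 35,
                            fixation_jitter_px = 1) {
  if (missing_prob < 0 || missing_prob > 1) {
    stop_cogload("invalid-input", "missing_prob must lie in [0, 1]")
  }
  structure(list(sampling_rate = sampling_rate,
                 fixation_duration = fixation_duration,
                 saccade_duration = saccade_duration,
                 pupil_baseline = pupil_baseline,
                 pupil_interval = pupil_interval,
                 pupil_noise_sd = pupil_noise_sd,
                 missing_prob = missing_prob, astigmatism = astigmatism,
                 px_per_deg = px_per_deg,
                 fixation_jitter_px = fixation_jitter_px),
            class = "gaze_sim_config")
}

#' Behavioural simulation configuration
#'
#' Lognormal reaction times and Bernoulli accuracy per condition, matched
#' by default to the modelled study's reported medians/means (RT medians
#' 1.06 s vs 1.43 s) and accuracy rates (0.94 vs 0.85). Draws exceeding the
#' stimulus timeout become timed-out (unanswered) trials.
#'
#' @param rt Per-condition lognormal parameters,
#'   `list(cond1 = list(meanlog, sdlog), cond2 = ...)`.
#' @param accuracy Per-condition probability that an answered scoreable
#'   trial is correct.
#' @return Object of class `behavior_sim_config`.
#' @export
behavior_sim_config <- function(rt = list(cond1 = rt_lognormal_params(1.06, 1.11),
                                          cond2 = rt_lognormal_params(1.43, 1.58)),
                                accuracy = c(cond1 = 0.94, cond2 = 0.85)) {
  if (any(accuracy < 0 | accuracy > 1)) {
    stop_cogload("invalid-input", "accuracy probabilities must lie in [0, 1]")
  }
  if (any(vapply(rt, function(p) p$sdlog <= 0, logical(1)))) {
    stop_cogload("invalid-input", "rt sdlog must be > 0")
  }
  structure(list(rt = rt, accuracy = accuracy), class = "behavior_sim_config")
}

#' Draw interval-level pupil dilation values
#'
#' Samples from the generator's per-condition interval-level dilation
#' distribution (the values the eye pipeline recovers as per-interval
#' averaged dilation, baseline removed).
#'
#' @param n Number of draws.
#' @param condition 1 or 2.
#' @param cfg A [gaze_sim_config()].
#' @return Numeric vector, mm.
#' @export
r_interval_dilation <- function(n, condition, cfg = gaze_sim_config()) {
  par <- cfg$pupil_interval[[paste0("cond", condition)]]
  r_shifted_lognormal(n, par)
}

# Gaussian-copula draw linking astigmatism (lognormal marginal) to the
# per-sample missing probability (logit-linear link), targeting a chosen
# population Spearman correlation between astigmatism and capture rate.
draw_astigmatism_missing <- function(n, rho = -0.55, astig_meanlog = log(100),
                                     astig_sdlog = 0.9, missing_base = 0.3,
                                     missing_spread = 1.5) {
  if (rho > 0) stop_cogload("invalid-input",
                            "coupling is specified for rho <= 0")
  # bivariate-normal Pearson r giving Spearman |rho| under the copula
  r <- 2 * sin(pi * abs(rho) / 6)
  z1 <- stats::rnorm(n)
  z2 <- r * z1 + sqrt(1 - r^2) * stats::rnorm(n)
  astig <- stats::qlnorm(stats::pnorm(z1), astig_meanlog, astig_sdlog)
  missing <- stats::plogis(stats::qlogis(missing_base) + missing_spread * z2)
  data.frame(astigmatism = astig, missing_prob = missing)
}

#' Simulate coupled astigmatism degrees and tracker capture rates
#'
#' Draws a cohort of participant astigmatism degrees and realized capture
#' rates under a monotone copula coupling whose population Spearman
#' correlation between astigmatism and capture rate equals `rho`
#' (default -0.55). The realized capture rate is binomial over `n_samples`
#' gaze samples at the participant's latent missing probability.
#'
#' @param n Number of participants.
#' @param rho Target population Spearman correlation (<= 0).
#' @param n_samples Gaze samples per participant used for the realization.
#' @param seed Optional integer seed.
#' @param ... Passed to the internal copula (`astig_meanlog`, `astig_sdlog`,
#'   `missing_base`, `missing_spread`).
#' @return Data frame with `astigmatism`, `missing_prob`, `capture_rate`.
#' @export
simulate_capture_astigmatism <- function(n, rho = -0.55, n_samples = 7800L,
                                         seed = NULL, ...) {
  with_seed(seed, {
    d <- draw_astigmatism_missing(n, rho = rho, ...)
    d$capture_rate <- stats::rbinom(n, n_samples, 1 - d$missing_prob) / n_samples
    d
  })
}

# --- session assembly ------------------------------------------------------

# Behavioural log of one block starting at time t0; returns the log rows and
# the block end time.
sim_block_log <- function(participant_id, letters, n_level, cond, t0,
                          task, behavior) {
  letters <- strsplit(letters, "")[[1L]]
  key <- derive_response_key(letters, n_level)
  rtp <- behavior$rt[[paste0("cond", cond)]]
  acc_p <- behavior$accuracy[[paste0("cond", cond)]]
  t <- t0
  rows <- vector("list", length(letters))
  for (i in seq_along(letters)) {
    onset <- t + stats::runif(1, task$isi_range[1], task$isi_range[2])
    rt <- stats::rlnorm(1, rtp$meanlog, rtp$sdlog)
    scoreable <- i > n_level
    if (rt > task$stimulus_timeout) {
      choice <- "none"; acc <- if (scoreable) "no" else "null"
      end <- onset + task$stimulus_timeout; rt_out <- NA_real_
    } else {
      end <- onset + rt; rt_out <- rt
      if (scoreable) {
        truth <- key[i - n_level] == "Y"
        ok <- stats::runif(1) < acc_p
        is_match <- if (ok) truth else !truth
        choice <- if (is_match) "match" else "nonmatch"
        acc <- if (ok) "yes" else "no"
      } else {
        choice <- if (stats::runif(1) < 0.5) "match" else "nonmatch"
        acc <- "null"
      }
    }
    rows[[i]] <- data.frame(id = participant_id, n_back = cond,
                            letter = letters[i], choice = choice,
                            accuracy = acc, reaction_time = rt_out,
                            start_unix = onset, end_unix = end)
    t <- end
  }
  list(log = do.call(rbind, rows), t_end = t)
}

sim_eeg <- function(task_log, t0, t_end, eeg) {
  fs <- eeg$sampling_rate
  n <- ceiling((t_end - t0) * fs) + 1L
  ts <- t0 + (seq_len(n) - 1L) / fs
  data <- matrix(0, n, length(eeg$channels),
                 dimnames = list(NULL, eeg$channels))
  act <- split(task_log[, c("start_unix", "end_unix")], task_log$n_back)
  for (ch in eeg$channels) {
    x <- pink_noise(n, eeg$noise_exponent, eeg$noise_amplitude)
    for (b in names(eeg$band_amplitudes)) {
      env <- rep(1, n)
      for (cond in names(act)) {
        d <- eeg$erd_truth$d[eeg$erd_truth$band == b &
                               eeg$erd_truth$channel == ch &
                               eeg$erd_truth$condition == as.integer(cond)]
        if (length(d) == 0L || d == 0) next
        for (k in seq_len(nrow(act[[cond]]))) {
          idx <- in_interval(ts, act[[cond]]$start_unix[k],
                             act[[cond]]$end_unix[k])
          env[idx] <- sqrt(1 - d)
        }
      }
      phase <- stats::runif(1, 0, 2 * pi)
      x <- x + eeg$band_amplitudes[[b]] * env *
        sin(2 * pi * eeg$band_freqs[[b]] * (ts - t0) + phase)
    }
    if (!identical(eeg$line_noise, "none")) {
      x <- x + eeg$line_amplitude *
        sin(2 * pi * as.numeric(eeg$line_noise) * (ts - t0))
    }
    data[, ch] <- x
  }
  eeg_recording(data, fs, t0)
}

sim_gaze <- function(task_log, timeline, t0, t_end, gaze) {
  fs <- gaze$sampling_rate
  ts <- seq(t0, t_end, by = 1 / fs)
  n <- length(ts)

  # which condition (1/2) governs an instant; 0 = rest/inter-stimulus
  block_of <- function(t) {
    for (k in seq_len(nrow(timeline))) {
      if (t >= timeline$start[k] && t < timeline$end[k] &&
          !is.na(timeline$condition[k])) {
        return(timeline$condition[k])
      }
    }
    0L
  }

  # alternate fixation / saccade events over the whole session
  evs <- list(); t <- t0; kind <- "fixation"
  while (t < t_end) {
    cond <- block_of(t)
    par_set <- if (kind == "fixation") gaze$fixation_duration else
      gaze$saccade_duration
    par <- par_set[[paste0("cond", max(cond, 1L))]]
    dur <- stats::rlnorm(1, par$meanlog, par$sdlog) / 1000
    evs[[length(evs) + 1L]] <- data.frame(
      kind = kind, start_ts = t, end_ts = min(t + dur, t_end),
      duration_ms = (min(t + dur, t_end) - t) * 1000)
    t <- t + dur
    kind <- if (kind == "fixation") "saccade" else "fixation"
  }
  events <- do.call(rbind, evs)

  # gaze positions: still (jittered) within fixations, linear jumps across
  # saccades
  x <- numeric(n); y <- numeric(n)
  px <- 0; py <- 0
  for (k in seq_len(nrow(events))) {
    idx <- in_interval(ts, events$start_ts[k], events$end_ts[k])
    if (events$kind[k] == "fixation") {
      if (length(idx)) {
        x[idx] <- px + stats::rnorm(length(idx), 0, gaze$fixation_jitter_px)
        y[idx] <- py + stats::rnorm(length(idx), 0, gaze$fixation_jitter_px)
      }
    } else {
      tx <- px + stats::rnorm(1, 0, 3 * gaze$px_per_deg)
      ty <- py + stats::rnorm(1, 0, 3 * gaze$px_per_deg)
      if (length(idx)) {
        frac <- (ts[idx] - events$start_ts[k]) /
          max(events$end_ts[k] - events$start_ts[k], 1e-9)
        x[idx] <- px + frac * (tx - px)
        y[idx] <- py + frac * (ty - py)
      }
      px <- tx; py <- ty
    }
  }

  # pupil: baseline + per-trial interval-level workload component + noise
  w <- numeric(n); truth_w <- numeric(nrow(task_log))
  for (k in seq_len(nrow(task_log))) {
    cond <- task_log$n_back[k]
    wk <- r_interval_dilation(1L, cond, gaze)
    truth_w[k] <- wk
    idx <- in_interval(ts, task_log$start_unix[k], task_log$end_unix[k])
    w[idx] <- wk
  }
  pl <- gaze$pupil_baseline + w + stats::rnorm(n, 0, gaze$pupil_noise_sd)
  pr <- gaze$pupil_baseline + w + stats::rnorm(n, 0, gaze$pupil_noise_sd)

  drop <- stats::runif(n) < gaze$missing_prob
  pl[drop] <- NA; pr[drop] <- NA; x[drop] <- NA; y[drop] <- NA
  samples <- data.frame(ts = ts, x = x, y = y, pupil_left = pl,
                        pupil_right = pr, valid_left = !drop,
                        valid_right = !drop)
  list(stream = gaze_stream(samples, events, fs), trial_dilation = truth_w)
}

#' Simulate one full experimental session
#'
#' Produces a complete synthetic session for one participant: the timeline
#' is a 10 s eyes-open rest, the first task block, a 5 s rest, then the
#' second block; block order follows [assign_orders()] parity. Behaviour,
#' EEG (band oscillations whose amplitude is scaled by `sqrt(1 - d)` inside
#' activation intervals, over 1/f noise) and gaze/pupil streams are
#' generated against that shared timeline, and every injected parameter is
#' recorded in the returned ground truth. Deterministic given `seed`.
#'
#' @param participant_id Integer ID (parity sets the block order).
#' @param task A [task_config()] providing the timing parameters.
#' @param eeg An [eeg_sim_config()], or `NULL` to skip the EEG stream.
#' @param gaze A [gaze_sim_config()], or `NULL` to skip the gaze stream.
#' @param behavior A [behavior_sim_config()].
#' @param sequences Letter sequences, as from [nback_sequences()].
#' @param session_start Unix time of session start.
#' @param seed Optional integer seed.
#' @return Object of class `session_bundle`: list with `participant_id`,
#'   `order`, `task_log`, `eeg`, `gaze`, `timeline`, `rest_interval` and
#'   `ground_truth`.
#' @export
simulate_session <- function(participant_id, task = task_config(),
                             eeg = eeg_sim_config(),
                             gaze = gaze_sim_config(),
                             behavior = behavior_sim_config(),
                             sequences = nback_sequences(),
                             session_start = 1.6e9, seed = NULL) {
  with_seed(seed, {
    order <- unname(assign_orders(participant_id))
    blocks <- if (order == "Order1") {
      list(list(seq = sequences$low, n = 1L), list(seq = sequences$high, n = 2L))
    } else {
      list(list(seq = sequences$high, n = 2L), list(seq = sequences$low, n = 1L))
    }
    t0 <- session_start
    rest1 <- c(t0, t0 + task$rest_eyes_open)
    b1 <- sim_block_log(participant_id, blocks[[1]]$seq, blocks[[1]]$n,
                        blocks[[1]]$n, rest1[2], task, behavior)
    rest2 <- c(b1$t_end, b1$t_end + task$rest_between_blocks)
    b2 <- sim_block_log(participant_id, blocks[[2]]$seq, blocks[[2]]$n,
                        blocks[[2]]$n, rest2[2], task, behavior)
    task_log <- rbind(b1$log, b2$log)
    t_end <- b2$t_end + 1
    timeline <- data.frame(
      segment = c("rest_eyes_open", "block1", "rest_between", "block2"),
      start = c(rest1[1], rest1[2], rest2[1], rest2[2]),
      end = c(rest1[2], rest2[1], rest2[2], b2$t_end),
      condition = c(NA, blocks[[1]]$n, NA, blocks[[2]]$n))

    # the recording device is started ~2 s before the rest marker, so no
    # event-locked window sits on the first samples of the stream
    eeg_rec <- if (!is.null(eeg)) sim_eeg(task_log, t0 - 2, t_end, eeg)
      else NULL
    gz <- if (!is.null(gaze)) sim_gaze(task_log, timeline, t0, t_end, gaze)
      else NULL

    truth <- list(
      participant_id = participant_id, order = order,
      erd_truth = if (!is.null(eeg)) eeg$erd_truth else NULL,
      pupil_interval_median = if (!is.null(gaze))
        c(cond1 = gaze$pupil_interval$cond1$median,
          cond2 = gaze$pupil_interval$cond2$median) else NULL,
      trial_dilation = if (!is.null(gz)) gz$trial_dilation else NULL,
      pupil_baseline = if (!is.null(gaze)) gaze$pupil_baseline else NULL,
      missing_prob = if (!is.null(gaze)) gaze$missing_prob else NULL,
      astigmatism = if (!is.null(gaze)) gaze$astigmatism else NULL,
      rt = behavior$rt, accuracy = behavior$accuracy)

    structure(list(participant_id = participant_id, order = order,
                   task_log = task_log, eeg = eeg_rec,
                   gaze = if (!is.null(gz)) gz$stream else NULL,
                   timeline = timeline, rest_interval = rest1,
                   dropout = FALSE, ground_truth = truth),
              class = "session_bundle")
  })
}

#' @export
print.session_bundle <- function(x, ...) {
  cat(sprintf("Session bundle: participant %d (%s)%s\n", x$participant_id,
              x$order, if (x$dropout) " [dropout: no streams]" else ""))
  if (!x$dropout) {
    cat(sprintf("  trials: %d;  EEG: %s;  gaze: %s\n", nrow(x$task_log),
                if (is.null(x$eeg)) "none" else "yes",
                if (is.null(x$gaze)) "none" else "yes"))
  }
  invisible(x)
}

#' Simulate a counterbalanced cohort of sessions
#'
#' Generates one [simulate_session()] bundle per participant with odd/even
#' ID counterbalancing, per-participant resting pupil baselines, and
#' astigmatism-coupled tracker missingness (population Spearman correlation
#' `astig_rho` between astigmatism and capture rate). IDs listed in
#' `dropout` produce bundles whose device streams are absent (flagged),
#' emulating recording failures.
#'
#' @param n_participants Cohort size (>= 2).
#' @param ids Participant IDs (default 101, 102, ...).
#' @param dropout IDs whose data are not recorded; defaults to ID 126 when
#'   present in `ids`.
#' @param task,eeg,gaze,behavior Module configurations (see the respective
#'   constructors); `eeg`/`gaze` may be `NULL` to skip a stream.
#' @param astig_rho Target astigmatism/capture-rate Spearman correlation
#'   (set `NULL` to keep each participant at `gaze$missing_prob`).
#' @param pupil_baseline_sd Between-participant SD of the resting pupil
#'   diameter, mm.
#' @param seed Integer seed (per-participant seeds derive from it).
#' @return Object of class `cohort`: list with `bundles` (named by ID) and
#'   `truth` (per-participant data frame: order, astigmatism, missing_prob,
#'   pupil baseline, dropout).
#' @export
simulate_cohort <- function(n_participants = 30L,
                            ids = seq(101L, length.out = n_participants),
                            dropout = intersect(126L, ids),
                            task = task_config(), eeg = eeg_sim_config(),
                            gaze = gaze_sim_config(),
                            behavior = behavior_sim_config(),
                            astig_rho = -0.55, pupil_baseline_sd = 0.3,
                            seed = 1L) {
  if (n_participants < 2L) {
    stop_cogload("invalid-input", "need n_participants >= 2")
  }
  ids <- as.integer(ids)
  cohort_draw <- with_seed(seed, {
    base <- if (!is.null(gaze)) gaze$pupil_baseline else 3.5
    miss <- if (!is.null(gaze)) gaze$missing_prob else 0.1
    d <- if (!is.null(astig_rho) && !is.null(gaze)) {
      draw_astigmatism_missing(length(ids), rho = astig_rho)
    } else {
      data.frame(astigmatism = rep(0, length(ids)),
                 missing_prob = rep(miss, length(ids)))
    }
    d$pupil_baseline <- stats::rnorm(length(ids), base, pupil_baseline_sd)
    d
  })
  bundles <- vector("list", length(ids))
  names(bundles) <- as.character(ids)
  for (j in seq_along(ids)) {
    id <- ids[j]
    if (id %in% dropout) {
      bundles[[j]] <- structure(
        list(participant_id = id, order = unname(assign_orders(id)),
             task_log = NULL, eeg = NULL, gaze = NULL, timeline = NULL,
             rest_interval = NULL, dropout = TRUE,
             ground_truth = list(participant_id = id)),
        class = "session_bundle")
      next
    }
    gz <- gaze
    if (!is.null(gz)) {
      gz$missing_prob <- cohort_draw$missing_prob[j]
      gz$astigmatism <- cohort_draw$astigmatism[j]
      gz$pupil_baseline <- cohort_draw$pupil_baseline[j]
    }
    bundles[[j]] <- simulate_session(
      id, task = task, eeg = eeg, gaze = gz, behavior = behavior,
      session_start = 1.6e9 + j * 1000, seed = child_seed(seed, id))
  }
  truth <- data.frame(id = ids, order = unname(assign_orders(ids)),
                      astigmatism = cohort_draw$astigmatism,
                      missing_prob = cohort_draw$missing_prob,
                      pupil_baseline = cohort_draw$pupil_baseline,
                      dropout = ids %in% dropout)
  structure(list(bundles = bundles, truth = truth), class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d participants (%d dropout)\n",
              nrow(x$truth), sum(x$truth$dropout)))
  cat(sprintf("  orders: %d Order1 / %d Order2\n",
              sum(x$truth$order == "Order1"), sum(x$truth$order == "Order2")))
  invisible(x)
}
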
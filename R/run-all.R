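# End-to-end orchestration: simulate (or load) a cohort, run all three
# pipelines, assemble the comparison tables, the screening report and the
# ground-truth recovery report.

#' Resolved run configuration
#'
#' Collects every analysis default in one nested document. Unknown keys are
#' rejected so that typos cannot silently fall back to defaults; the
#' resolved configuration (and its hash) is embedded in every [run_all()]
#' result.
#'
#' @param ... Overrides of the defaults: `seed`, `n_participants`, `ids`,
#'   `dropout`, `bands`, `baseline` (`"near"`/`"away"`), `notch`,
#'   `min_capture_rate`, `adjust`, `min_rest_pupil_samples`, and the module
#'   configurations `task`, `eeg`, `gaze`, `behavior`, `astig_rho`.
#' @return Object of class `run_config` (named list) with attribute `hash`.
#' @export
run_config <- function(...) {
  defaults <- list(
    seed = 1L,
    n_participants = 30L,
    ids = NULL,             # default: 101..(100 + n_participants)
    dropout = NULL,         # default: 126 when present
    task = task_config(),
    eeg = eeg_sim_config(),
    gaze = gaze_sim_config(),
    behavior = behavior_sim_config(),
    astig_rho = -0.55,
    bands = band_defs(),
    baseline = "near",
    notch = NULL,
    min_capture_rate = 0.6,
    min_rest_pupil_samples = 10L,
    adjust = "none")
  dots <- list(...)
  unknown <- setdiff(names(dots), names(defaults))
  if (length(unknown)) {
    stop_cogload("configuration",
                 paste("unknown config key(s):", paste(unknown, collapse = ", ")))
  }
  cfg <- utils::modifyList(defaults, dots, keep.null = TRUE)
  cfg$ids <- cfg$ids %||% seq(101L, length.out = cfg$n_participants)
  cfg$dropout <- cfg$dropout %||% intersect(126L, cfg$ids)
  structure(cfg, class = "run_config",
            hash = config_hash(cfg[setdiff(names(cfg), "hash")]))
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf("Run configuration [hash %s]\n", attr(x, "hash")))
  cat(sprintf("  cohort: n = %d, seed = %d, dropout: %s\n", x$n_participants,
              x$seed, paste(x$dropout, collapse = ", ")))
  cat(sprintf("  baseline: %s;  screening threshold: %.2f;  adjust: %s\n",
              x$baseline, x$min_capture_rate, x$adjust))
  invisible(x)
}

# Process one session bundle: behavioural rows, per-trial ERD rows (near
# and away), per-interval eye rows, capture rate. Returns NULL components
# where a stream is absent.
process_session <- function(bundle, cfg) {
  if (bundle$dropout) return(NULL)
  log <- bundle$task_log
  rest <- bundle$rest_interval
  id <- bundle$participant_id

  # behaviour: per-block scoring
  behav <- lapply(split(log, log$n_back), function(bl) {
    n <- bl$n_back[1]
    key <- derive_response_key(bl$letter, n)
    s <- score_block(bl, key, cfg$task$stimulus_timeout)
    data.frame(id = id, condition = n, accuracy_rate = s$accuracy_rate,
               n_timeout = s$n_timeout)
  })
  scoreable <- unlist(lapply(split(seq_len(nrow(log)), log$n_back),
                             function(ix) ix[-seq_len(log$n_back[ix[1]])]))
  keep <- intersect(which(log$choice != "none" & !is.na(log$reaction_time)),
                    scoreable)

  out <- list(
    behavioral = do.call(rbind, behav),
    rt = if (length(keep)) data.frame(id = id, condition = log$n_back[keep],
                                      rt = log$reaction_time[keep]) else NULL)

  if (!is.null(bundle$eeg)) {
    out$erd_near <- erd_table(bundle$eeg, log, rest[1], bands = cfg$bands,
                              baseline = "near", notch = cfg$notch,
                              stimulus_timeout = cfg$task$stimulus_timeout)
    out$erd_away <- erd_table(bundle$eeg, log, rest[1], bands = cfg$bands,
                              baseline = "away", notch = cfg$notch,
                              stimulus_timeout = cfg$task$stimulus_timeout)
    out$erd_near$id <- id
    out$erd_away$id <- id
  }

  if (!is.null(bundle$gaze)) {
    out$capture <- as.numeric(capture_rate(bundle$gaze))
    bl <- tryCatch(
      pupil_baseline(bundle$gaze, rest,
                     min_valid = cfg$min_rest_pupil_samples),
      error = function(e) NULL)
    if (!is.null(bl)) {
      iv <- segment_trials(log, rest[1], cfg$task$stimulus_timeout)
      act <- iv[iv$kind == "activation", ]
      em <- interval_metrics(bundle$gaze, act, bl)
      em$id <- id
      out$eye <- em
    }
  }
  out
}

#' Run the full analysis end-to-end on a synthetic cohort
#'
#' Simulates a cohort under the resolved configuration, runs the task,
#' EEG and eye pipelines on every recorded session, and assembles: the
#' behavioural comparison table (reaction time pooled over trials — overall
#' and by ID parity — and per-participant accuracy rate), the 12-measure
#' near-baseline ERD table and the away-baseline table, the eye-metric
#' comparison tables, the capture-rate screening report, the
#' astigmatism/capture-rate Spearman correlation, and a ground-truth
#' recovery report. Deterministic given `config$seed`.
#'
#' @param config A [run_config()].
#' @return Object of class `cogload_run`: list with `tables` (named
#'   [comparison_table()]s), `screening`, `astigmatism` (a
#'   [spearman_cor()] result), `recovery`, `exclusions`, `config`.
#' @export
run_all <- function(config = run_config()) {
  cfg <- config
  cohort <- simulate_cohort(
    n_participants = cfg$n_participants, ids = cfg$ids, dropout = cfg$dropout,
    task = cfg$task, eeg = cfg$eeg, gaze = cfg$gaze, behavior = cfg$behavior,
    astig_rho = cfg$astig_rho, seed = cfg$seed)

  proc <- lapply(cohort$bundles, process_session, cfg = cfg)
  proc <- proc[!vapply(proc, is.null, logical(1))]

  pull <- function(el) {
    parts <- lapply(proc, `[[`, el)
    parts <- parts[!vapply(parts, is.null, logical(1))]
    if (length(parts) == 0L) return(NULL)
    do.call(rbind, lapply(parts, as.data.frame))
  }

  # ---- behaviour ----------------------------------------------------------
  rt <- pull("rt")
  behav <- pull("behavioral")
  perf <- rbind(
    data.frame(measure = "Reaction time", condition = rt$condition,
               value = rt$rt, id = rt$id),
    data.frame(measure = "Reaction time (odd IDs)",
               condition = rt$condition[rt$id %% 2 == 1],
               value = rt$rt[rt$id %% 2 == 1], id = rt$id[rt$id %% 2 == 1]),
    data.frame(measure = "Reaction time (even IDs)",
               condition = rt$condition[rt$id %% 2 == 0],
               value = rt$rt[rt$id %% 2 == 0], id = rt$id[rt$id %% 2 == 0]),
    data.frame(measure = "Accuracy rate", condition = behav$condition,
               value = behav$accuracy_rate, id = behav$id))
  tables <- list(performance = comparison_table(perf, adjust = cfg$adjust))

  # ---- EEG ---------------------------------------------------------------
  near <- pull("erd_near")
  if (!is.null(near)) {
    lab <- function(d, suffix) {
      kind <- ifelse(d$band == "Theta", "ERS", "ERD")
      data.frame(measure = paste(d$band, kind, d$channel, suffix, sep = "_"),
                 condition = d$condition, value = d$value_fraction)
    }
    tables$eeg_near <- comparison_table(lab(near, "near"), adjust = cfg$adjust)
    away <- pull("erd_away")
    away <- away[(away$band == "Alpha" & away$channel == "AF7") |
                   (away$band == "Beta" & away$channel == "TP9"), ]
    tables$eeg_away <- comparison_table(lab(away, "away"), adjust = cfg$adjust)
  }

  # ---- eye movement ------------------------------------------------------
  screening <- NULL; astig <- NULL
  eye_measures <- c("avg_pupil_dilation_left", "avg_pupil_dilation_right",
                    "avg_fixation_duration", "fixation_number_per_second",
                    "avg_saccade_duration", "saccade_number_per_second",
                    "max_pupil_dilation_left", "max_pupil_dilation_right",
                    "max_fixation_duration", "max_saccade_duration")
  caps <- vapply(proc, function(p) p$capture %||% NA_real_, numeric(1))
  caps <- caps[!is.na(caps)]
  eye <- NULL
  if (length(caps)) {
    screening <- filter_participants(caps, cfg$min_capture_rate)
    eye <- pull("eye")
    if (!is.null(eye)) {
      eye <- eye[as.character(eye$id) %in% screening$included, ]
      long <- do.call(rbind, lapply(eye_measures, function(mm) {
        data.frame(measure = mm, condition = eye$condition, value = eye[[mm]])
      }))
      if (nrow(eye)) {
        tables$eye <- comparison_table(long, measures = eye_measures,
                                       adjust = cfg$adjust)
      }
    }
    if (length(caps) >= 3L) {
      tr <- cohort$truth[!cohort$truth$dropout, ]
      astig <- spearman_cor(
        tr$astigmatism[match(as.integer(names(caps)), tr$id)],
        as.numeric(caps))
    }
  }

  # ---- ground-truth recovery ---------------------------------------------
  recovery <- list()
  if (!is.null(near)) {
    est <- summary(structure(near, class = c("erd_table", "data.frame")))
    truth <- cfg$eeg$erd_truth
    est$truth_d <- truth$d[match(paste(est$band, est$channel, est$condition),
                                 paste(truth$band, truth$channel,
                                       truth$condition))]
    est$abs_error <- abs(est$mean_fraction - est$truth_d)
    recovery$erd <- est
  }
  if (length(caps) && !is.null(eye) && nrow(eye)) {
    med <- vapply(split(eye$avg_pupil_dilation_left, eye$condition),
                  stats::median, numeric(1), na.rm = TRUE)
    recovery$pupil <- data.frame(
      condition = as.integer(names(med)), median_estimate = as.numeric(med),
      truth_median = c(cfg$gaze$pupil_interval$cond1$median,
                       cfg$gaze$pupil_interval$cond2$median)[
                         as.integer(names(med))])
    tr <- cohort$truth[!cohort$truth$dropout, ]
    recovery$capture <- data.frame(
      id = as.integer(names(caps)), realized = as.numeric(caps),
      expected = 1 - tr$missing_prob[match(as.integer(names(caps)), tr$id)])
  }

  exclusions <- list(
    dropout = cfg$dropout,
    erd_excluded = if (!is.null(near))
      sum(vapply(proc, function(p)
        nrow(attr(p$erd_near, "excluded") %||% data.frame()), numeric(1)))
      else 0)

  structure(list(tables = tables, screening = screening, astigmatism = astig,
                 recovery = recovery, exclusions = exclusions,
                 config = cfg),
            class = "cogload_run")
}

#' @export
print.cogload_run <- function(x, ...) {
  cat(sprintf("cogload end-to-end run [config %s]\n", attr(x$config, "hash")))
  cat("\n-- Behavioural comparisons --\n")
  print(x$tables$performance)
  if (!is.null(x$tables$eeg_near)) {
    cat("\n-- ERD/ERS comparisons (near baseline) --\n")
    print(x$tables$eeg_near)
  }
  if (!is.null(x$tables$eye)) {
    cat("\n-- Eye-movement comparisons (screened cohort) --\n")
    print(x$tables$eye)
  }
  if (!is.null(x$screening)) print(x$screening)
  if (!is.null(x$astigmatism)) {
    cat("Astigmatism vs capture rate: ")
    print(x$astigmatism)
  }
  invisible(x)
}
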
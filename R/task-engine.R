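#' Configuration of an N-back block
#'
#' Bundles the timing and alphabet parameters of an N-back working-memory
#' block. The defaults mirror a common smartphone deployment: each letter
#' stays on screen for at most 3 s, inter-stimulus intervals are drawn
#' uniformly from 1--2 s, blocks are separated by a 5 s rest, and each
#' session opens with a 10 s eyes-open rest used as the resting baseline.
#'
#' @param n_level Integer >= 1, the "N" of N-back (1 = compare with the
#'   previous letter, 2 = two letters back, ...).
#' @param stimulus_timeout Maximum stimulus duration in seconds.
#' @param isi_range Length-2 numeric, lower/upper bound of the uniformly
#'   sampled inter-stimulus interval, seconds.
#' @param rest_between_blocks Rest between the two task blocks, seconds.
#' @param rest_eyes_open Eyes-open rest at session start, seconds.
#' @param alphabet Character vector of allowed (uppercase) stimulus letters.
#' @return An object of class `task_config`.
#' @export
task_config <- function(n_level = 1L, stimulus_timeout = 3,
                        isi_range = c(1, 2), rest_between_blocks = 5,
                        rest_eyes_open = 10, alphabet = LETTERS) {
  n_level <- as.integer(n_level)
  if (is.na(n_level) || n_level < 1L) {
    stop_cogload("invalid-input", "n_level must be an integer >= 1")
  }
  if (!is.numeric(stimulus_timeout) || stimulus_timeout <= 0) {
    stop_cogload("invalid-input", "stimulus_timeout must be > 0")
  }
  if (length(isi_range) != 2L || isi_range[1] > isi_range[2]) {
    stop_cogload("invalid-input", "isi_range must be c(low, high), low <= high")
  }
  alphabet <- toupper(alphabet)
  if (!all(grepl("^[A-Z]$", alphabet))) {
    stop_cogload("invalid-input", "alphabet must contain single letters only")
  }
  structure(
    list(n_level = n_level, stimulus_timeout = stimulus_timeout,
         isi_range = as.numeric(isi_range),
         rest_between_blocks = rest_between_blocks,
         rest_eyes_open = rest_eyes_open, alphabet = alphabet),
    class = "task_config")
}

#' Published N-back letter sequences
#'
#' The fixed letter sets used by the experiment this package models: two
#' short training blocks plus the two experiment blocks. The low-workload
#' block is scored as 1-back and the high-workload block as 2-back; the two
#' experiment sequences are constructed so that they share one and the same
#' response key (derive it with [derive_response_key()]).
#'
#' @return Named list of letter strings with elements `training_low`,
#'   `training_high`, `low` (1-back block) and `high` (2-back block).
#' @export
nback_sequences <- function() {
  list(training_low  = "EEIPP",
       training_high = "OSOMLI",
       low  = "DAABEEDRRODHHRDSSELDD",
       high = "BAEAAEASHSAELEOBBBOSHS")
}

#' Derive the match/non-match response key of a letter sequence
#'
#' Applies the N-back rule: the entry for a scoreable stimulus is `"Y"` when
#' the letter equals the one presented `n_level` positions earlier and `"N"`
#' otherwise. The first `n_level` stimuli are unscoreable and produce no
#' entry, so the key has `max(0, length - n_level)` entries.
#'
#' @param letters A single string or a character vector of single letters.
#' @param n_level Integer >= 1.
#' @return Character vector of `"Y"`/`"N"` flags.
#' @examples
#' derive_response_key("EEIPP", 1)              # "Y" "N" "N" "Y"
#' key_low  <- derive_response_key(nback_sequences()$low, 1)
#' key_high <- derive_response_key(nback_sequences()$high, 2)
#' identical(key_low, key_high)                 # TRUE: shared key by design
#' @export
derive_response_key <- function(letters, n_level) {
  if (length(letters) == 1L && nchar(letters[[1L]]) > 1L) {
    letters <- strsplit(letters[[1L]], "")[[1L]]
  }
  letters <- toupper(as.character(letters))
  if (length(letters) == 0L) {
    stop_cogload("invalid-input", "letter sequence is empty")
  }
  if (!all(grepl("^[A-Z]$", letters))) {
    stop_cogload("invalid-input", "sequence contains non-letter symbols")
  }
  n_level <- as.integer(n_level)
  if (is.na(n_level) || n_level < 1L) {
    stop_cogload("invalid-input", "n_level must be an integer >= 1")
  }
  n <- length(letters)
  if (n <= n_level) return(character(0))
  idx <- (n_level + 1L):n
  ifelse(letters[idx] == letters[idx - n_level], "Y", "N")
}

#' Generate a letter sequence realising a chosen response key
#'
#' Constructs a sequence whose [derive_response_key()] equals `key` at the
#' given `n_level`. The first `n_level` letters are free draws; each further
#' letter is forced to repeat (key `"Y"`) or avoid (key `"N"`) the letter
#' `n_level` positions back. Deterministic given `seed`.
#'
#' @param n_level Integer >= 1.
#' @param key Character vector of `"Y"`/`"N"` flags (or one string).
#' @param alphabet Candidate letters; must contain at least two letters when
#'   the key holds any `"N"`.
#' @param seed Optional integer seed.
#' @return A single uppercase string.
#' @export
generate_sequence <- function(n_level, key, alphabet = LETTERS, seed = NULL) {
  if (length(key) == 1L && nchar(key[[1L]]) > 1L) {
    key <- strsplit(key[[1L]], "")[[1L]]
  }
  key <- toupper(key)
  if (length(key) == 0L) {
    stop_cogload("invalid-input", "target key must be nonempty")
  }
  if (!all(key %in% c("Y", "N"))) {
    stop_cogload("invalid-input", "key entries must be 'Y' or 'N'")
  }
  alphabet <- toupper(alphabet)
  n_level <- as.integer(n_level)
  if (any(key == "N") && length(unique(alphabet)) < 2L) {
    stop_cogload("generation",
                 "alphabet with a single letter cannot realise an 'N' entry")
  }
  with_seed(seed, {
    out <- resample(alphabet, 1L)
    if (n_level > 1L) {
      out <- c(out, sample(alphabet, n_level - 1L, replace = TRUE))
    }
    for (k in key) {
      ref <- out[length(out) - n_level + 1L]
      nxt <- if (k == "Y") ref else resample(setdiff(alphabet, ref))
      out <- c(out, nxt)
    }
    paste(out, collapse = "")
  })
}

#' Assign counterbalanced block orders by participant ID parity
#'
#' Odd IDs run Order 1 (low workload block first, then high); even IDs run
#' Order 2 (high first). This cancels block-order effects across a cohort
#' with balanced parity.
#'
#' @param participant_ids Integer vector of IDs.
#' @return Named character vector, `"Order1"` or `"Order2"` per ID.
#' @export
assign_orders <- function(participant_ids) {
  if (length(participant_ids) == 0L) {
    stop_cogload("invalid-input", "participant_ids is empty")
  }
  ids <- as.integer(participant_ids)
  out <- ifelse(ids %% 2L == 1L, "Order1", "Order2")
  names(out) <- as.character(ids)
  out
}

#' Score a block of trial records against its response key
#'
#' Computes per-trial reaction times (`response - onset`, seconds) and the
#' accuracy rate AR = correct inputs / scoreable inputs. The last
#' `length(key)` rows of `trials` are the scoreable stimuli; earlier rows
#' (the first `n_level` stimuli) are unscoreable and excluded from the
#' denominator. Timed-out trials (no response) count as incorrect and
#' contribute no reaction time.
#'
#' @param trials Data frame ordered by onset with columns `onset_ts`,
#'   `response_ts` (NA when timed out) and `choice`
#'   (`"match"`/`"nonmatch"`/`"none"`). Optional columns `participant_id`,
#'   `block_label` are carried through.
#' @param key Character vector of `"Y"`/`"N"` flags, as from
#'   [derive_response_key()].
#' @param stimulus_timeout Upper bound accepted for reaction times, seconds.
#' @return An object of class `behavioral_summary` with elements
#'   `rt_values`, `accuracy_rate`, `n_scoreable`, `n_correct`, `n_timeout`.
#' @export
score_block <- function(trials, key, stimulus_timeout = 3) {
  if (length(key) == 1L && nchar(key[[1L]]) > 1L) {
    key <- strsplit(key[[1L]], "")[[1L]]
  }
  n_key <- length(key)
  if (n_key == 0L) stop_cogload("alignment", "response key is empty")
  if (!is.data.frame(trials) || nrow(trials) < n_key) {
    stop_cogload("alignment",
                 sprintf("need >= %d trials for a %d-entry key", n_key, n_key))
  }
  if (is.unsorted(trials$onset_ts, strictly = TRUE)) {
    stop_cogload("data-integrity", "trial onsets must be strictly increasing")
  }
  sc <- trials[(nrow(trials) - n_key + 1L):nrow(trials), , drop = FALSE]
  answered <- !is.na(sc$response_ts) & sc$choice != "none"
  rt <- sc$response_ts[answered] - sc$onset_ts[answered]
  if (any(rt <= 0 | rt > stimulus_timeout + 1e-9)) {
    stop_cogload("data-integrity",
                 "answered reaction times must lie in (0, stimulus_timeout]")
  }
  correct <- answered & ((sc$choice == "match") == (key == "Y"))
  structure(
    list(participant_id = trials$participant_id[1L] %||% NA_integer_,
         block_label = trials$block_label[1L] %||% NA_character_,
         rt_values = as.numeric(rt),
         accuracy_rate = sum(correct) / n_key,
         n_scoreable = n_key,
         n_correct = sum(correct),
         n_timeout = sum(!answered)),
    class = "behavioral_summary")
}

#' @export
print.behavioral_summary <- function(x, ...) {
  cat(sprintf("N-back block summary (participant %s, block %s)\n",
              x$participant_id, x$block_label))
  cat(sprintf("  scoreable: %d  correct: %d  timeouts: %d\n",
              x$n_scoreable, x$n_correct, x$n_timeout))
  cat(sprintf("  accuracy rate: %.3f\n", x$accuracy_rate))
  if (length(x$rt_values)) {
    cat(sprintf("  reaction time: median %.3f s (n = %d)\n",
                stats::median(x$rt_values), length(x$rt_values)))
  }
  invisible(x)
}
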
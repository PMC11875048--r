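# Independent brute-force oracles and fixture builders used across tests.
# The oracles deliberately use naive explicit loops, never the package's own
# windowed-scan code paths.

random_outcome_trials <- function(n, p_none = 0.1, p_correct = 0.6) {
  rewarded_side <- sample(c("left", "right"), n, replace = TRUE)
  resp <- ifelse(runif(n) < p_none, "none",
                 ifelse(runif(n) < p_correct, rewarded_side,
                        ifelse(rewarded_side == "left", "right", "left")))
  correct <- ifelse(resp == "none", NA, resp == rewarded_side)
  tibble::tibble(
    trial_index = seq_len(n),
    stage_id = "SD",
    block_index = 0L,
    whisker_stim = "W1",
    odor_stim = NA_character_,
    rewarded_side = rewarded_side,
    congruent = NA,
    first_response = resp,
    correct = correct,
    rewarded = !is.na(correct) & correct,
    reward_volume_ul = ifelse(!is.na(correct) & correct, 4, 0),
    relevant_modality = "whisker",
    t_start_ms = seq_len(n) * 10000L,
    t_end_ms = seq_len(n) * 10000L + 4500L,
    iti_ms = 9000L
  )
}

make_log <- function(trials, config = stage_config("SD"),
                     terminated_by = "no_response_run") {
  structure(
    list(config = config, trials = trials,
         events = tibble::tibble(t_ms = integer(0), trial_index = integer(0),
                                 kind = character(0), side = character(0),
                                 exemplar = character(0),
                                 volume_ul = numeric(0),
                                 shift_type = character(0),
                                 rule_before = character(0),
                                 rule_after = character(0)),
         shifts = tibble::tibble(trial_index = integer(0),
                                 shift_type = character(0),
                                 rule_before = character(0),
                                 rule_after = character(0)),
         total_volume_ul = sum(trials$reward_volume_ul),
         terminated_by = terminated_by,
         final_rule = NULL, final_agent = NULL),
    class = "session_log"
  )
}

# naive trailing-window accuracy at each trial position
brute_moving_accuracy <- function(trials, w) {
  n <- nrow(trials)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    cc <- trials$correct[seq_len(i)][trials$first_response[seq_len(i)] != "none"]
    if (length(cc) >= w) out[i] <- mean(cc[(length(cc) - w + 1):length(cc)])
  }
  out
}

# naive first response-trial index at which trailing-window accuracy passes
brute_ttc <- function(trials, w, thr) {
  cc <- trials$correct[trials$first_response != "none"]
  if (length(cc) < w) return(NA_integer_)
  for (k in w:length(cc)) {
    if (mean(cc[(k - w + 1):k]) >= thr) return(k)
  }
  NA_integer_
}

# naive fourfold discrimination-stage pass decision
brute_sd_pass <- function(trials, cr) {
  if (!(nrow(trials) > cr$min_trials)) return(FALSE)
  resp <- trials[trials$first_response != "none", ]
  cc <- resp$correct
  acc_ok <- FALSE
  w <- cr$accuracy_window
  if (length(cc) >= w) {
    for (s in 1:(length(cc) - w + 1)) {
      if (mean(cc[s:(s + w - 1)]) >= cr$accuracy_threshold) acc_ok <- TRUE
    }
  }
  if (!acc_ok) return(FALSE)
  bal_ok <- FALSE
  bw <- cr$side_balance$window
  if (nrow(resp) >= bw) {
    for (s in 1:(nrow(resp) - bw + 1)) {
      win <- resp[s:(s + bw - 1), ]
      l <- win$correct[win$rewarded_side == "left"]
      r <- win$correct[win$rewarded_side == "right"]
      if (length(l) && length(r) &&
          mean(l) > cr$side_balance$threshold &&
          mean(r) > cr$side_balance$threshold) {
        bal_ok <- TRUE
      }
    }
  }
  if (!bal_ok) return(FALSE)
  mean(trials$first_response != "none") > cr$response_rate_min
}

brute_trigger <- function(correct_seq, w, thr) {
  n <- length(correct_seq)
  n >= w && mean(correct_seq[(n - w + 1):n]) >= thr
}

# Shared validator: every emitted trial/event record satisfies its contract.
validate_session_log <- function(log) {
  tr <- log$trials
  resp <- tr$first_response != "none"
  expect_true(all(tr$correct[resp] ==
                    (tr$first_response[resp] == tr$rewarded_side[resp])))
  expect_true(all(is.na(tr$correct[!resp])))
  expect_true(all(tr$reward_volume_ul[tr$rewarded] == log$config$droplet_ul))
  expect_true(all(tr$reward_volume_ul[!tr$rewarded] == 0))
  expect_equal(log$total_volume_ul, sum(tr$reward_volume_ul))
  ev <- log$events
  for (i in tr$trial_index) {
    e <- ev[!is.na(ev$trial_index) & ev$trial_index == i &
              ev$kind != "session_end", ]
    expect_true(all(diff(e$t_ms) >= 0) || all(e$t_ms == sort(e$t_ms)))
    expect_equal(sum(e$kind == "trial_start"), 1)
    expect_equal(sum(e$kind == "trial_end"), 1)
    t0 <- e$t_ms[e$kind == "trial_start"]
    t1 <- e$t_ms[e$kind == "trial_end"]
    expect_true(all(e$t_ms >= t0 & e$t_ms <= t1))
    # trial-cueing stimulus onsets only (the post-lick HB3B flash is a
    # reward-predicting event, not a cue)
    stim_on <- e$t_ms[e$kind %in% c("whisker_on", "odor_command_on") &
                        (is.na(e$exemplar) | e$exemplar != "flash")]
    win_on <- e$t_ms[e$kind == "response_window_on"]
    if (length(stim_on)) expect_true(all(win_on >= min(stim_on)))
  }
  invisible(log)
}

# Independent post-hoc switch audit: within each block, the first trial at
# which the trailing 30-response-trial accuracy reaches 0.80 (scanning
# trial-by-trial, naively) must be exactly where the switch was logged.
audit_switches <- function(log, w = 30L, thr = 0.80) {
  tr <- log$trials
  bounds <- c(0L, log$shifts$trial_index, nrow(tr))
  for (b in seq_len(length(bounds) - 1L)) {
    lo <- bounds[b] + 1L
    hi <- bounds[b + 1L]
    cc <- logical(0)
    fired_at <- NA_integer_
    if (lo > hi) next  # a switch on the final trial leaves an empty tail
    for (i in lo:hi) {
      if (tr$first_response[i] != "none") cc <- c(cc, tr$correct[i])
      if (length(cc) >= w && mean(cc[(length(cc) - w + 1):length(cc)]) >= thr) {
        fired_at <- i
        break
      }
    }
    if (b < length(bounds) - 1L) {
      # this block ended in a logged switch: it must sit exactly at the
      # first trigger point
      if (!identical(fired_at, hi)) return(FALSE)
    } else {
      # terminal open block: no trigger point may precede session end
      if (!is.na(fired_at)) return(FALSE)
    }
  }
  TRUE
}

other_side_acc <- function(s) ifelse(s == "left", "right", "left")
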
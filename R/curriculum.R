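STAGE_ORDER <- c("HB1", "HB2", "HB3", "HB3B", "SH4", "SH5", "SD", "CD")
TERMINAL_STAGE <- "set_shifting"

#' Stage definitions for the training curriculum
#'
#' One row per curriculum stage: its reward-side schedule, which modalities
#' are presented, which reward-rule semantics apply, and the pass criterion
#' family. Habituation stages pass on consumed volume (500 ul); `SH5` on an
#' 80% / 100-trial accuracy window; simple (`SD`) and compound (`CD`)
#' discrimination on the fourfold criterion.
#'
#' @return a tibble of stage definitions in protocol order.
#' @export
stage_table <- function() {
  tibble(
    stage_id = STAGE_ORDER,
    schedule = c("alternating_armed", "alternating_armed", "blocked",
                 "blocked", "blocked", "blocked", "randomized", "randomized"),
    stimuli_present = c("none", "none", "none", "whisker_flash",
                        "whisker", "whisker", "whisker", "whisker+odor"),
    reward_rule = c(rep("any_correct_lick", 5), rep("first_lick_correct", 3)),
    iti_profile = c(rep("habituation_timeout", 4), rep("shaping", 2),
                    rep("task", 2)),
    pass_on = c(rep("volume", 5), "accuracy_window", "fourfold", "fourfold")
  )
}

#' Evaluate whether a session passes its stage's criterion
#'
#' Habituation and `SH4` pass on consuming the volume target (500 ul).
#' `SH5` passes when any 100-response-trial window reaches 80% accuracy.
#' `SD` and `CD` require all four: (1) more than 100 trials performed,
#' (2) 80% accuracy in a 30-trial moving window, (3) one 10-trial window in
#' which accuracy on left trials and on right trials both exceed 50%
#' simultaneously, and (4) a response on more than 80% of trials. Accuracy
#' windows count response trials only; thresholds phrased as "reach 80%" are
#' inclusive.
#'
#' @param log a `session_log`.
#' @param stage_id stage token; must match the log's stage.
#' @return list `(passed, detail)`; `detail` is a tibble with one row per
#'   criterion (`criterion`, `satisfied`, `value`, `threshold`,
#'   `met_at_trial` for the accuracy window).
#' @export
evaluate_stage_pass <- function(log, stage_id = log$config$stage_id) {
  if (!identical(stage_id, log$config$stage_id)) {
    abort(paste0("log was produced under stage '", log$config$stage_id,
                 "', not '", stage_id, "'"))
  }
  cr <- log$config$criteria
  trials <- log$trials
  rows <- list()
  add <- function(criterion, satisfied, value, threshold,
                  met_at_trial = NA_integer_) {
    rows[[length(rows) + 1L]] <<- tibble(
      criterion = criterion, satisfied = satisfied, value = value,
      threshold = threshold, met_at_trial = as.integer(met_at_trial))
  }

  if (!is.null(cr$volume_target_ul)) {
    add("volume", log$total_volume_ul >= cr$volume_target_ul,
        log$total_volume_ul, cr$volume_target_ul)
  } else {
    if (!is.null(cr$min_trials)) {
      add("min_trials", nrow(trials) > cr$min_trials, nrow(trials),
          cr$min_trials)
    }
    met <- accuracy_window_met_at(trials, cr$accuracy_window,
                                  cr$accuracy_threshold)
    add("accuracy_window", !is.na(met),
        best_window_accuracy(trials, cr$accuracy_window),
        cr$accuracy_threshold, met_at_trial = met)
    if (!is.null(cr$side_balance)) {
      add("side_balance",
          side_balance_met(trials, cr$side_balance$window,
                           cr$side_balance$threshold),
          NA_real_, cr$side_balance$threshold)
    }
    if (!is.null(cr$response_rate_min)) {
      rr <- mean(trials$first_response != "none")
      add("response_rate", rr > cr$response_rate_min, rr,
          cr$response_rate_min)
    }
  }
  detail <- dplyr::bind_rows(rows)
  list(passed = all(detail$satisfied), detail = detail)
}

# Global trial index at which the trailing accuracy window is first
# satisfied, NA if never.
accuracy_window_met_at <- function(trials, window, threshold) {
  resp <- which(trials$first_response != "none")
  cc <- trials$correct[resp]
  n <- length(cc)
  if (n < window) return(NA_integer_)
  cs <- c(0, cumsum(cc))
  ks <- window:n
  acc <- (cs[ks + 1L] - cs[ks - window + 1L]) / window
  hit <- which(acc >= threshold)
  if (!length(hit)) return(NA_integer_)
  resp[ks[hit[1]]]
}

best_window_accuracy <- function(trials, window) {
  cc <- trials$correct[trials$first_response != "none"]
  if (length(cc) < window) return(NA_real_)
  cs <- c(0, cumsum(cc))
  max((cs[(window + 1):length(cs)] - cs[1:(length(cs) - window)]) / window)
}

# One window of `window` consecutive response trials in which accuracy on
# left-rewarded and right-rewarded trials both strictly exceed `threshold`.
side_balance_met <- function(trials, window, threshold) {
  resp <- trials[trials$first_response != "none", ]
  n <- nrow(resp)
  if (n < window) return(FALSE)
  for (s in 1:(n - window + 1L)) {
    win <- resp[s:(s + window - 1L), ]
    lacc <- mean(win$correct[win$rewarded_side == "left"])
    racc <- mean(win$correct[win$rewarded_side == "right"])
    if (!is.na(lacc) && !is.na(racc) && lacc > threshold && racc > threshold) {
      return(TRUE)
    }
  }
  FALSE
}

#' Next curriculum stage
#'
#' Protocol order HB1, HB2, HB3, HB3B, SH4, SH5, SD, CD; a failed stage
#' repeats, a passed `CD` graduates to the set-shifting task (terminal
#' token `"set_shifting"`).
#'
#' @param current current stage token.
#' @param passed did the session pass the stage criterion?
#' @return the next stage token.
#' @export
next_stage <- function(current, passed) {
  i <- match(current, STAGE_ORDER)
  if (is.na(i)) abort(paste0("unknown stage '", current, "'"))
  if (!passed) return(current)
  if (i == length(STAGE_ORDER)) TERMINAL_STAGE else STAGE_ORDER[i + 1L]
}

#' Run the full training curriculum
#'
#' Sequential daily sessions with the agent's learned associations and
#' attention carried across sessions; each stage repeats until its criterion
#' is passed, then advances. Per-session seeds are derived from the
#' curriculum seed and session index so any session is reproducible in
#' isolation.
#'
#' @param agent an [agent_state()].
#' @param configs named list of per-stage [session_config()] overrides;
#'   missing stages use [stage_config()] defaults.
#' @param max_sessions stop (with `truncated = TRUE`) after this many
#'   sessions if the terminal stage is not reached.
#' @param seed curriculum seed.
#' @param rule initial [rule_state()].
#' @return a `curriculum_history`: list with `sessions` (tibble: stage,
#'   session index, pass flag, summaries), `logs`, `truncated`,
#'   `final_stage`, `final_agent`.
#' @export
run_curriculum <- function(agent, configs = list(), max_sessions = 40L,
                           seed = 1L, rule = rule_state()) {
  stage <- STAGE_ORDER[1]
  rows <- list()
  logs <- list()
  k <- 0L
  while (stage != TERMINAL_STAGE && k < max_sessions) {
    k <- k + 1L
    cfg <- configs[[stage]] %||% stage_config(stage)
    cfg$seed <- derive_seed(seed, k)
    log <- run_session(cfg, rule, agent)
    agent <- log$final_agent
    ev <- evaluate_stage_pass(log)
    rows[[k]] <- dplyr::bind_cols(
      tibble(session_index = k, stage_id = stage, passed = ev$passed),
      glance(log)[c("n_trials", "response_rate", "total_volume_ul",
                    "terminated_by")]
    )
    logs[[k]] <- log
    stage <- next_stage(stage, ev$passed)
  }
  structure(
    list(sessions = dplyr::bind_rows(rows), logs = logs,
         truncated = stage != TERMINAL_STAGE, final_stage = stage,
         final_agent = agent),
    class = "curriculum_history"
  )
}

#' @export
print.curriculum_history <- function(x, ...) {
  cat("<curriculum_history>", nrow(x$sessions), "sessions; reached",
      x$final_stage, if (x$truncated) "(truncated)" else "", "\n")
  invisible(x)
}

#' Tidy a curriculum history into its per-session table
#'
#' @param x a `curriculum_history`.
#' @param ... unused.
#' @export
tidy.curriculum_history <- function(x, ...) x$sessions
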
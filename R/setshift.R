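#' Draw the rewarded side, optionally correcting for lick bias
#'
#' With bias correction disabled each side is drawn with probability 0.5.
#' Enabled, the probability of arming the left spout equals the animal's
#' recent frequency of responding right, clamped to `[pmin, pmax]` — i.e.
#' the likelihood of a reward location is weighted in inverse relation to
#' how often the animal has been choosing it, which breaks stereotyped
#' response strategies during training. An empty history counts as balanced
#' (0.5).
#'
#' @param recent_responses character vector of the most recent response
#'   sides (at most the configured window).
#' @param bias_cfg `list(enabled, window, clamp = c(pmin, pmax))`.
#' @return `"left"` or `"right"`.
#' @export
draw_reward_side <- function(recent_responses,
                             bias_cfg = list(enabled = TRUE, window = 20L,
                                             clamp = c(0.1, 0.9))) {
  if (!isTRUE(bias_cfg$enabled)) {
    return(sample(SIDES, 1L))
  }
  f_right <- if (length(recent_responses) == 0) 0.5
             else mean(recent_responses == "right")
  p_left <- min(bias_cfg$clamp[2], max(bias_cfg$clamp[1], f_right))
  if (runif(1) < p_left) "left" else "right"
}

#' Compose a compound trial for the current rule
#'
#' The relevant modality contributes the exemplar its latent map sends to
#' the rewarded side; the irrelevant (distractor) modality contributes one
#' of its two active exemplars drawn uniformly. The trial is congruent when
#' both maps send their chosen exemplars to the same side, so over many
#' draws half of trials are congruent.
#'
#' @param rule a [rule_state()].
#' @param rewarded_side `"left"` or `"right"`.
#' @return list `(whisker_stim, odor_stim, congruent)`.
#' @export
compose_trial <- function(rule, rewarded_side) {
  rel <- relevant_map(rule)
  if (!rewarded_side %in% rel) {
    abort(paste0("rewarded side '", rewarded_side,
                 "' is not in the relevant map's image"))
  }
  rel_stim <- names(rel)[rel == rewarded_side]
  irr <- irrelevant_map(rule)
  irr_stim <- sample(names(irr), 1L)
  if (rule$relevant_modality == "whisker") {
    w <- rel_stim; o <- irr_stim
  } else {
    w <- irr_stim; o <- rel_stim
  }
  list(whisker_stim = w, odor_stim = o,
       congruent = unname(rule$whisker_map[w] == rule$odor_map[o]))
}

# Trailing-window trigger on the current block's response-trial outcomes.
trigger_fires <- function(block_resp_correct, window, threshold) {
  n <- length(block_resp_correct)
  n >= window && mean(block_resp_correct[(n - window + 1L):n]) >= threshold
}

#' Should a rule switch be triggered?
#'
#' In serial set-shifting sessions a covert rule switch fires when the
#' animal attains the criterion accuracy (default 80%, inclusive) within the
#' trailing moving window (default 30) of response trials of the current
#' block. No-response trials do not count toward the window.
#'
#' @param block_trials tibble of the current block's trials (needs
#'   `first_response` and `correct`).
#' @param window moving-window length in response trials.
#' @param threshold accuracy threshold (inclusive).
#' @return logical.
#' @export
check_switch_trigger <- function(block_trials, window = 30L,
                                 threshold = 0.80) {
  cc <- block_trials$correct[block_trials$first_response != "none"]
  trigger_fires(cc, window, threshold)
}

#' Controller for serial set-shifting sessions
#'
#' Holds the shift sequence and the trigger parameters used by
#' [run_session()]. The default sequence is alternating extradimensional
#' shifts (whisker rule to odor rule and back); arbitrary sequences mixing
#' `"EDS"`, `"Rev"` and `"IDS"` are accepted and recycled.
#'
#' @param shift_sequence character vector of shift types, recycled.
#' @param window,threshold trigger parameters (see
#'   [check_switch_trigger()]).
#' @return a `seds_controller` list.
#' @export
seds_controller <- function(shift_sequence = "EDS", window = 30L,
                            threshold = 0.80) {
  stopifnot(all(shift_sequence %in% c("EDS", "Rev", "IDS")),
            length(shift_sequence) >= 1)
  structure(list(shift_sequence = shift_sequence, window = as.integer(window),
                 threshold = threshold),
            class = "seds_controller")
}

#' Run a serial set-shifting (SEDS) session
#'
#' Runs trials through the trial engine, drawing reward sides (with optional
#' lick-bias correction) and composing compound whisker + odor stimuli for
#' the current rule; after each trial, if the trailing 30-response-trial
#' accuracy of the current block reaches 80%, the next shift in the sequence
#' is applied covertly (the agent receives no cue) and logged as a
#' `rule_switch` event carrying the full before/after mappings.
#'
#' @param config a [session_config()] (stage `"SEDS"`).
#' @param initial_rule a [rule_state()].
#' @param agent an [agent_state()].
#' @param shift_sequence shift types, recycled (default alternating EDS).
#' @param pools exemplar pools.
#' @return a `session_log` (see [run_session()]).
#' @export
run_seds_session <- function(config, initial_rule, agent,
                             shift_sequence = "EDS",
                             pools = exemplar_pools()) {
  ctl <- seds_controller(shift_sequence,
                         window = config$criteria$accuracy_window,
                         threshold = config$criteria$accuracy_threshold)
  run_session(config, initial_rule, agent, controller = ctl, pools = pools)
}
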
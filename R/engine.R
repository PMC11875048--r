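#' Reward rule for a trial's response-window licks
#'
#' Habituation and the first shaping stage (`HB*`, `SH4`) use permissive
#' semantics: a reward is delivered if any lick hits the rewarded side, even
#' after licks to the other side. From `SH5` onward the first lick in the
#' response window must be to the rewarded side. `first_response` is the
#' side of the first window lick (or `"none"`), and `correct` compares it to
#' the rewarded side (`NA` on no-response).
#'
#' @param stage_id stage token; decides which semantics apply.
#' @param licks tibble/data frame with columns `t_ms` and `side`, restricted
#'   to the response window and time-sorted.
#' @param rewarded_side `"left"` or `"right"`.
#' @return list `(first_response, correct, rewarded, reward_t_ms)`;
#'   `reward_t_ms` is the qualifying lick time or `NA`.
#' @export
apply_reward_rule <- function(stage_id, licks, rewarded_side) {
  rule <- stage_reward_rule(stage_id)
  if (length(licks$t_ms) == 0) {
    return(list(first_response = "none", correct = NA, rewarded = FALSE,
                reward_t_ms = NA_integer_))
  }
  first_response <- licks$side[1]
  correct <- first_response == rewarded_side
  if (rule == "any_correct_lick") {
    hit <- which(licks$side == rewarded_side)
    rewarded <- length(hit) > 0
    reward_t <- if (rewarded) licks$t_ms[hit[1]] else NA_integer_
  } else {
    rewarded <- correct
    reward_t <- if (rewarded) licks$t_ms[1] else NA_integer_
  }
  list(first_response = first_response, correct = correct,
       rewarded = rewarded, reward_t_ms = as.integer(reward_t))
}

stage_reward_rule <- function(stage_id) {
  switch(stage_id,
    HB1 = , HB2 = , HB3 = , HB3B = , SH4 = "any_correct_lick",
    SH5 = , SD = , CD = , SEDS = "first_lick_correct",
    abort(paste0("unknown stage '", stage_id, "'"))
  )
}

#' Schedule an optogenetic TTL pulse train
#'
#' Pulse onsets at a fixed period of `1000 / frequency_hz` ms starting at
#' t = 0, truncated at `duration_ms` (onsets strictly before the duration).
#' Models the logged TTL command train only; no light delivery is simulated.
#'
#' @param frequency_hz pulse frequency (> 0).
#' @param duration_ms train duration.
#' @param pulse_width_ms width of each pulse; must be below the period.
#' @return tibble with columns `ttl_pulse_on`, `ttl_pulse_off` (ms).
#' @export
schedule_pulse_train <- function(frequency_hz, duration_ms, pulse_width_ms) {
  stopifnot(frequency_hz > 0, duration_ms > 0)
  period <- 1000 / frequency_hz
  if (pulse_width_ms >= period) {
    abort("pulse_width_ms must be smaller than the pulse period")
  }
  n_on <- ceiling(duration_ms * frequency_hz / 1000 - 1e-9)
  on <- (seq_len(n_on) - 1) * period
  tibble(ttl_pulse_on = as.integer(round(on)),
         ttl_pulse_off = as.integer(round(on + pulse_width_ms)))
}

# Internal mutable event accumulator: chunked lists (O(n) appends), one
# tibble at the end.
new_event_buffer <- function() {
  env <- new.env(parent = emptyenv())
  for (f in c("t", "trial", "kind", "side", "exemplar", "volume",
              "shift_type", "rule_before", "rule_after")) {
    env[[f]] <- vector("list", 0L)
  }
  env$n <- 0L
  env
}

push_events <- function(buf, t, kind, trial = NA_integer_, side = NA_character_,
                        exemplar = NA_character_, volume = NA_real_,
                        shift_type = NA_character_,
                        rule_before = NA_character_,
                        rule_after = NA_character_) {
  n <- length(t)
  i <- buf$n + 1L
  buf$n <- i
  buf$t[[i]] <- as.integer(t)
  buf$trial[[i]] <- rep_len(as.integer(trial), n)
  buf$kind[[i]] <- rep_len(kind, n)
  buf$side[[i]] <- rep_len(side, n)
  buf$exemplar[[i]] <- rep_len(exemplar, n)
  buf$volume[[i]] <- rep_len(volume, n)
  buf$shift_type[[i]] <- rep_len(shift_type, n)
  buf$rule_before[[i]] <- rep_len(rule_before, n)
  buf$rule_after[[i]] <- rep_len(rule_after, n)
  invisible(buf)
}

buffer_to_events <- function(buf) {
  ev <- fast_tibble(t_ms = unlist(buf$t, use.names = FALSE),
               trial_index = unlist(buf$trial, use.names = FALSE),
               kind = unlist(buf$kind, use.names = FALSE),
               side = unlist(buf$side, use.names = FALSE),
               exemplar = unlist(buf$exemplar, use.names = FALSE),
               volume_ul = unlist(buf$volume, use.names = FALSE),
               shift_type = unlist(buf$shift_type, use.names = FALSE),
               rule_before = unlist(buf$rule_before, use.names = FALSE),
               rule_after = unlist(buf$rule_after, use.names = FALSE))
  ev[order(ev$t_ms, seq_len(nrow(ev))), ]
}

fast_tibble <- function(...) {
  cols <- list(...)
  tibble::new_tibble(cols, nrow = length(cols[[1]]))
}

event_row <- function(t, kind, trial = NA_integer_, side = NA_character_,
                      exemplar = NA_character_, volume = NA_real_,
                      shift_type = NA_character_,
                      rule_before = NA_character_,
                      rule_after = NA_character_) {
  fast_tibble(t_ms = as.integer(t), trial_index = as.integer(trial),
              kind = kind, side = side, exemplar = exemplar,
              volume_ul = volume, shift_type = shift_type,
              rule_before = rule_before, rule_after = rule_after)
}

#' Run a single trial
#'
#' Deterministic (given the RNG state) discrete-event simulation of one
#' trial: trial start, the 500 ms onset tone, stimulus onsets at tone offset
#' (the odorant reaches the nose `odor_onset_latency_ms` after its command),
#' the response window opening `stim_ms` after stimulus onset and lasting
#' `response_window_ms`, the agent's licks, and reward or omission. Only
#' response-window licks enter the reward rule; anticipatory licks during
#' the stimulus epoch are logged but never rewarded. In `SH4` and earlier,
#' reward is delivered at the time of the first rewarded-side lick; the
#' trial then ends immediately.
#'
#' @param spec list with `whisker_stim`, `odor_stim` (exemplar ids or `NA`),
#'   `rewarded_side`, and optional `explore_both`.
#' @param rule a [rule_state()].
#' @param agent an [agent_state()]; errors if already satiated.
#' @param config a [session_config()].
#' @param t0 session-clock time of trial start (ms).
#' @param trial_index 1-based trial number.
#' @return list `(trial, events, agent, t_end)`; `trial` is a one-row
#'   tibble, `events` the trial's event tibble.
#' @export
run_trial <- function(spec, rule, agent, config, t0 = 0L, trial_index = 1L) {
  if (agent$satiated) {
    abort("agent is satiated; end the session (see agent_rest())")
  }
  buf <- new_event_buffer()
  w <- spec$whisker_stim %||% NA_character_
  o <- spec$odor_stim %||% NA_character_
  stim_on <- t0 + config$tone_ms
  win_on <- stim_on + config$stim_ms
  win_end <- win_on + config$response_window_ms

  push_events(buf, t0, "trial_start", trial_index)
  if (config$tone_ms > 0) {
    push_events(buf, t0, "tone_on", trial_index)
    push_events(buf, t0 + config$tone_ms, "tone_off", trial_index)
  }
  if (!is.na(w)) {
    push_events(buf, stim_on, "whisker_on", trial_index, exemplar = w)
    push_events(buf, win_on, "whisker_off", trial_index, exemplar = w)
  }
  if (!is.na(o)) {
    push_events(buf, stim_on, "odor_command_on", trial_index, exemplar = o)
    push_events(buf, stim_on + config$odor_onset_latency_ms, "odor_nose_on",
                trial_index, exemplar = o)
  }
  push_events(buf, win_on, "response_window_on", trial_index)

  ch <- agent_choose(agent, w, o,
                     timing = list(stim_on = stim_on, win_on = win_on,
                                   win_end = win_end),
                     explore_both = isTRUE(spec$explore_both))
  in_win <- ch$lick_times >= win_on & ch$lick_times <= win_end
  licks <- list(t_ms = ch$lick_times[in_win], side = ch$lick_sides[in_win])
  out <- apply_reward_rule(config$stage_id, licks, spec$rewarded_side)

  reward_t <- out$reward_t_ms
  if (out$rewarded && config$stage_id == "HB3B") {
    # brief whisker flash between the qualifying lick and water delivery
    flash <- draw_ms(config$hb3b_whisker_flash_ms)
    push_events(buf, reward_t, "whisker_on", trial_index, exemplar = "flash")
    push_events(buf, reward_t + flash, "whisker_off", trial_index,
                exemplar = "flash")
    reward_t <- reward_t + flash
  }
  if (out$rewarded) {
    push_events(buf, reward_t,
                if (spec$rewarded_side == "left") "reward_left"
                else "reward_right",
                trial_index, side = spec$rewarded_side,
                volume = config$droplet_ul)
    t_end <- reward_t
  } else if (out$first_response == "none") {
    push_events(buf, win_end, "omission", trial_index)
    t_end <- win_end
  } else {
    t_end <- win_end
  }
  # licks are logged only within the trial span (post-reward licks spill
  # into the ITI and are not part of the trial record)
  keep <- ch$lick_times <= t_end
  if (any(keep)) {
    push_events(buf, ch$lick_times[keep],
                ifelse(ch$lick_sides[keep] == "left", "lick_left",
                       "lick_right"),
                trial_index, side = ch$lick_sides[keep])
  }
  if (!is.na(o)) {
    # passive odorant clearing, clamped to the trial (bookkeeping only)
    push_events(buf, min(win_on + config$odor_clear_ms, t_end), "odor_off",
                trial_index, exemplar = o)
  }
  push_events(buf, t_end, "trial_end", trial_index)

  agent$trials_done <- agent$trials_done + 1L
  agent$session_trials <- agent$session_trials + 1L

  trial <- tibble::new_tibble(list(
    trial_index = as.integer(trial_index),
    stage_id = config$stage_id,
    block_index = rule$block_index,
    whisker_stim = w, odor_stim = o,
    rewarded_side = spec$rewarded_side,
    congruent = trial_congruent(rule, w, o),
    first_response = out$first_response,
    correct = out$correct,
    rewarded = out$rewarded,
    reward_volume_ul = if (out$rewarded) config$droplet_ul else 0,
    relevant_modality = rule$relevant_modality,
    t_start_ms = as.integer(t0), t_end_ms = as.integer(t_end),
    iti_ms = NA_integer_
  ), nrow = 1L)
  list(trial = trial, events = buffer_to_events(buf), agent = agent,
       t_end = as.integer(t_end))
}
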
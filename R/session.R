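#' Run a whole session
#'
#' Deterministic (given `config$seed`) discrete-event simulation of one
#' behavioral session: iterates trials, drawing the rewarded side from the
#' stage's schedule (or from the set-shifting controller when supplied),
#' lets the agent respond and learn, appends a uniformly drawn intertrial
#' interval after each trial, and stops at the first satisfied termination
#' condition: the configured run of consecutive no-response trials
#' (satiety), the consumed-volume target, the trial cap, or — in the early
#' habituation stages — the two-minute-without-reward rule (recorded as
#' `"manual"`, the experimenter ending the session).
#'
#' @param config a valid [session_config()].
#' @param rule a [rule_state()].
#' @param agent an [agent_state()]; it is re-armed ([agent_rest()]) at
#'   session start and carried through learning.
#' @param controller optional set-shift controller from [seds_controller()].
#' @param pools exemplar pools.
#' @return a `session_log`: list with `config`, `trials` (tibble),
#'   `events` (tibble), `shifts` (tibble), `total_volume_ul`,
#'   `terminated_by`, `final_rule`, `final_agent`.
#' @export
run_session <- function(config, rule, agent, controller = NULL,
                        pools = exemplar_pools()) {
  viol <- validate_config(config)
  if (length(viol)) {
    abort(paste0("invalid config: ", paste(viol, collapse = "; ")))
  }
  withr::local_seed(config$seed)
  agent <- agent_rest(agent)

  trials <- vector("list", config$trial_cap)
  ev_list <- vector("list", 2L * config$trial_cap + 1L)
  n_ev <- 0L
  shifts <- list()
  t <- 0L
  vol <- 0
  last_reward_t <- 0L
  no_resp_run <- 0L
  resp_history <- character(0)
  block_resp_correct <- logical(0)
  n_shifts <- 0L
  terminated_by <- "trial_cap"
  first_armed <- sample(SIDES, 1L)
  hb3_sched <- hb3_block_schedule(config$trial_cap)

  i <- 0L
  while (i < config$trial_cap) {
    i <- i + 1L
    if (is.null(controller)) {
      spec <- stage_trial_spec(config$stage_id, i, rule, config, first_armed,
                               hb3_sched, resp_history)
    } else {
      side <- draw_reward_side(tail(resp_history, config$bias_correction$window),
                               config$bias_correction)
      cmp <- compose_trial(rule, side)
      spec <- list(whisker_stim = cmp$whisker_stim, odor_stim = cmp$odor_stim,
                   rewarded_side = side)
    }
    res <- run_trial(spec, rule, agent, config, t0 = t, trial_index = i)
    n_ev <- n_ev + 1L
    ev_list[[n_ev]] <- res$events
    agent <- res$agent
    trial <- res$trial
    rule$trials_in_block <- rule$trials_in_block + 1L

    responded <- trial$first_response != "none"
    if (responded) {
      no_resp_run <- 0L
      resp_history <- c(resp_history, trial$first_response)
      if (length(resp_history) > 200L) {
        resp_history <- tail(resp_history, config$bias_correction$window)
      }
      block_resp_correct <- c(block_resp_correct, trial$correct)
      agent <- agent_update(agent, trial)
    } else {
      no_resp_run <- no_resp_run + 1L
    }
    vol <- vol + trial$reward_volume_ul
    if (trial$rewarded) last_reward_t <- res$t_end

    # performance-triggered covert rule switch (set-shifting controller)
    if (!is.null(controller) &&
        trigger_fires(block_resp_correct, controller$window,
                      controller$threshold)) {
      n_shifts <- n_shifts + 1L
      st <- controller$shift_sequence[(n_shifts - 1L) %%
                                        length(controller$shift_sequence) + 1L]
      se <- apply_shift(rule, st, pools)
      se$trial_index <- i
      n_ev <- n_ev + 1L
      ev_list[[n_ev]] <- event_row(res$t_end, "rule_switch", i,
                                   shift_type = st,
                                   rule_before = encode_rule(se$rule_before),
                                   rule_after = encode_rule(se$rule_after))
      shifts[[n_shifts]] <- se
      rule <- se$rule_after
      block_resp_correct <- logical(0)
    }

    iti <- draw_ms(config$iti_range_ms)
    trial$iti_ms <- iti
    trials[[i]] <- trial
    t <- res$t_end + iti

    if (!is.null(config$volume_pass_ul) && vol >= config$volume_pass_ul) {
      terminated_by <- "volume_target"
      break
    }
    if (no_resp_run >= config$no_response_termination) {
      terminated_by <- "no_response_run"
      agent$satiated <- TRUE
      break
    }
    if (!is.null(config$no_reward_timeout_ms) &&
        res$t_end - last_reward_t >= config$no_reward_timeout_ms) {
      terminated_by <- "manual"
      break
    }
  }
  trials <- dplyr::bind_rows(trials[seq_len(i)])
  n_ev <- n_ev + 1L
  ev_list[[n_ev]] <- event_row(t, "session_end", i)
  events <- dplyr::bind_rows(ev_list[seq_len(n_ev)])
  structure(
    list(config = config, trials = trials, events = events,
         shifts = shift_table(shifts),
         total_volume_ul = vol, terminated_by = terminated_by,
         final_rule = rule, final_agent = agent),
    class = "session_log"
  )
}

shift_table <- function(shifts) {
  if (!length(shifts)) {
    return(tibble(trial_index = integer(0), shift_type = character(0),
                  rule_before = character(0), rule_after = character(0)))
  }
  tibble(
    trial_index = vapply(shifts, function(s) s$trial_index, 1L),
    shift_type = vapply(shifts, function(s) s$shift_type, ""),
    rule_before = vapply(shifts, function(s) encode_rule(s$rule_before), ""),
    rule_after = vapply(shifts, function(s) encode_rule(s$rule_after), "")
  )
}

# HB3 blocks the armed side in incrementally increasing runs, capped at 20.
hb3_block_schedule <- function(n) {
  lens <- c(5L, 10L, 15L)
  lens <- c(lens, rep(20L, ceiling(max(0, n - sum(lens)) / 20) + 1L))
  rep(seq_along(lens) %% 2L, times = lens)[seq_len(n)]
}

stage_trial_spec <- function(stage_id, i, rule, config, first_armed,
                             hb3_sched, resp_history) {
  alt <- function(flip) {
    if (flip) other_side(first_armed) else first_armed
  }
  wmap <- rule$whisker_map
  stim_for <- function(map, side) names(map)[map == side]
  switch(stage_id,
    HB1 = ,
    HB2 = list(whisker_stim = NA_character_, odor_stim = NA_character_,
               rewarded_side = alt(i %% 2L == 0L), explore_both = TRUE),
    HB3 = ,
    HB3B = list(whisker_stim = NA_character_, odor_stim = NA_character_,
                rewarded_side = alt(hb3_sched[i] == 0L), explore_both = TRUE),
    SH4 = ,
    SH5 = {
      side <- alt(((i - 1L) %/% 20L) %% 2L == 1L)
      list(whisker_stim = stim_for(wmap, side), odor_stim = NA_character_,
           rewarded_side = side)
    },
    SD = {
      side <- draw_reward_side(tail(resp_history, config$bias_correction$window),
                               config$bias_correction)
      list(whisker_stim = stim_for(wmap, side), odor_stim = NA_character_,
           rewarded_side = side)
    },
    CD = {
      side <- draw_reward_side(tail(resp_history, config$bias_correction$window),
                               config$bias_correction)
      list(whisker_stim = stim_for(wmap, side),
           odor_stim = sample(names(rule$odor_map), 1L),
           rewarded_side = side)
    },
    abort(paste0("unknown stage '", stage_id, "'"))
  )
}

#' @export
print.session_log <- function(x, ...) {
  cat("<session_log> stage", x$config$stage_id,
      "|", nrow(x$trials), "trials |",
      nrow(x$shifts), "rule switches |",
      x$total_volume_ul, "ul | terminated by", x$terminated_by, "\n")
  invisible(x)
}

#' Tidy a session log into its per-trial table
#'
#' @param x a `session_log`.
#' @param ... unused.
#' @return the trials tibble.
#' @export
tidy.session_log <- function(x, ...) x$trials

#' One-row summary of a session log
#'
#' @param x a `session_log`.
#' @param ... unused.
#' @return a one-row tibble with trial, block, response-rate, volume and
#'   termination summaries.
#' @export
glance.session_log <- function(x, ...) {
  resp <- x$trials$first_response != "none"
  tibble(
    stage_id = x$config$stage_id,
    n_trials = nrow(x$trials),
    n_blocks = nrow(x$shifts) + 1L,
    n_switches = nrow(x$shifts),
    response_rate = mean(resp),
    accuracy = mean(x$trials$correct[resp]),
    total_volume_ul = x$total_volume_ul,
    terminated_by = x$terminated_by
  )
}
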
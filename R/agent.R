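#' Agent parameters
#'
#' Parameters of the simulated mouse: an attention-weighted two-alternative
#' choice model with trial-by-trial learning, lapses, side bias, stochastic
#' responding, anticipatory licking and satiety. The model is deliberately
#' the simplest mechanism that produces the phenomena the analytics must
#' detect: graded acquisition toward criterion, perseveration confined to
#' incongruent trials after covert rule switches, side bias for the
#' bias-correction scheduler, and satiety-driven session termination.
#'
#' @param attn_whisker0 initial attention weight on the whisker modality, in
#'   \code{[0, 1]}; the odor weight is its complement.
#' @param assoc_lr learning rate in (0, 1] for exemplar-to-side association
#'   strengths.
#' @param attn_lr learning rate in (0, 1] for attention reallocation.
#' @param inv_temp decision sharpness (inverse temperature) of the logistic
#'   choice rule; 0 is random, large values are near-deterministic.
#' @param lapse probability of a uniformly random choice regardless of
#'   evidence.
#' @param side_bias additive bias toward the right spout, in decision
#'   (log-odds) units.
#' @param p_respond per-trial probability of making any response before
#'   satiety.
#' @param satiety_trials mean number of trials before satiety; the actual
#'   satiety point is drawn per session (normal, SD 50, truncated at 1),
#'   after which the agent stops responding.
#' @param lick_rate_hz anticipatory lick frequency (default 8 Hz).
#' @param seed_offset integer mixed into per-agent seed derivation.
#' @return an `agent_params` list.
#' @export
agent_params <- function(attn_whisker0 = 0.5, assoc_lr = 0.2, attn_lr = 0.1,
                         inv_temp = 3, lapse = 0.1, side_bias = 0,
                         p_respond = 0.95, satiety_trials = 450,
                         lick_rate_hz = 8, seed_offset = 0L) {
  stopifnot(attn_whisker0 >= 0, attn_whisker0 <= 1,
            assoc_lr >= 0, assoc_lr <= 1, attn_lr >= 0, attn_lr <= 1,
            inv_temp >= 0, lapse >= 0, lapse <= 1,
            p_respond > 0, p_respond <= 1, lick_rate_hz > 0)
  structure(
    list(attn_whisker0 = attn_whisker0, assoc_lr = assoc_lr,
         attn_lr = attn_lr, inv_temp = inv_temp, lapse = lapse,
         side_bias = side_bias, p_respond = p_respond,
         satiety_trials = satiety_trials, lick_rate_hz = lick_rate_hz,
         seed_offset = as.integer(seed_offset)),
    class = "agent_params"
  )
}

#' Agent state
#'
#' Mutable state of a simulated mouse: its parameters, the current whisker
#' attention weight, signed association strengths per exemplar (+1 means the
#' exemplar predicts a right reward, -1 a left reward), a trial counter and a
#' satiety flag. Association strengths stay bounded in \code{[-1, +1]}.
#'
#' @param params an [agent_params()].
#' @param pools exemplar pools used to initialize association strengths at 0.
#' @param assoc optional named numeric vector of initial association
#'   strengths (overrides the zero initialization).
#' @return an `agent_state` list.
#' @export
agent_state <- function(params = agent_params(), pools = exemplar_pools(),
                        assoc = NULL) {
  a <- setNames(numeric(nrow(pools)), pools$exemplar_id)
  if (!is.null(assoc)) a[names(assoc)] <- pmin(pmax(assoc, -1), 1)
  structure(
    list(params = params, attn_whisker = params$attn_whisker0, assoc = a,
         trials_done = 0L, session_trials = 0L,
         satiety_point = Inf, satiated = FALSE),
    class = "agent_state"
  )
}

#' Re-arm an agent for a new session
#'
#' Clears the satiety flag and draws a fresh per-session satiety point
#' (normal with mean `satiety_trials` and SD 50, truncated at 1 trial), as a
#' water-restricted animal is re-motivated between daily sessions. Learned
#' associations and attention carry over.
#'
#' @param agent an [agent_state()].
#' @return the refreshed `agent_state`.
#' @export
agent_rest <- function(agent) {
  agent$satiated <- FALSE
  agent$session_trials <- 0L
  agent$satiety_point <- max(1, round(rnorm(1, agent$params$satiety_trials, 50)))
  agent
}

# Decision-variable evidence for the presented stimuli; an absent stimulus
# contributes nothing and its attention weight is renormalized away.
agent_evidence <- function(attn_whisker, assoc, whisker_stim, odor_stim) {
  hw <- !is.na(whisker_stim); ho <- !is.na(odor_stim)
  if (hw && ho) {
    attn_whisker * assoc[[whisker_stim]] +
      (1 - attn_whisker) * assoc[[odor_stim]]
  } else if (hw) {
    assoc[[whisker_stim]]
  } else if (ho) {
    assoc[[odor_stim]]
  } else {
    0
  }
}

#' Simulate one choice and its lick train
#'
#' With probability `1 - p_respond` (or always, once the session's satiety
#' point is passed) the agent makes no response. Otherwise, with probability
#' `lapse` it picks a side uniformly; else it computes the attention-weighted
#' evidence for the presented stimuli and chooses right with probability
#' `plogis(inv_temp * evidence + side_bias)`. The lick train runs from
#' stimulus onset to the response at `lick_rate_hz` (intervals jittered
#' +/-10%), all toward the chosen side; the first lick inside the response
#' window is the response.
#'
#' @param state an [agent_state()].
#' @param whisker_stim,odor_stim exemplar ids or `NA`.
#' @param timing list with `stim_on`, `win_on`, `win_end` (ms, session
#'   clock); defaults describe a standalone trial at time 0.
#' @param explore_both if `TRUE` (habituation, where no stimulus instructs a
#'   side) the agent samples both spouts alternately within the window,
#'   starting from the chosen side.
#' @return `list(response = "left"|"right"|"none", lick_times, lick_sides)`.
#' @export
agent_choose <- function(state, whisker_stim = NA, odor_stim = NA,
                         timing = list(stim_on = 0L, win_on = 2500L,
                                       win_end = 4000L),
                         explore_both = FALSE) {
  p <- state$params
  p_resp <- if (state$session_trials >= state$satiety_point) 0 else p$p_respond
  if (runif(1) >= p_resp) {
    return(list(response = "none", lick_times = integer(0),
                lick_sides = character(0)))
  }
  if (runif(1) < p$lapse) {
    side <- sample(SIDES, 1L)
  } else {
    ev <- agent_evidence(state$attn_whisker, state$assoc,
                         whisker_stim, odor_stim)
    side <- if (runif(1) < plogis(p$inv_temp * ev + p$side_bias)) "right"
            else "left"
  }
  period <- 1000 / p$lick_rate_hz
  if (timing$win_on > timing$stim_on) {
    # anticipatory train through the stimulus epoch, ending at the first
    # lick inside the response window (the response)
    n_max <- ceiling((timing$win_end - timing$stim_on) / (0.9 * period)) + 2L
    gaps <- period * runif(n_max, 0.9, 1.1)
    t <- as.integer(round(timing$stim_on + cumsum(gaps)))
    stop_at <- which(t >= timing$win_on)[1]
    t <- t[seq_len(stop_at)]
    t <- t[t <= timing$win_end]
    sides <- rep(side, length(t))
  } else {
    t <- as.integer(timing$win_on + sample(100:600, 1L))
    sides <- side
    if (explore_both) {
      extra <- as.integer(round(t + period * seq_len(3L)))
      keep <- extra <= timing$win_end
      t <- c(t, extra[keep])
      sides <- c(side, rep(c(other_side(side), side), length.out = 3L)[keep])
    }
  }
  list(response = side, lick_times = t, lick_sides = sides)
}

#' Update associations and attention after a trial
#'
#' Full-information learning: after a response, each presented exemplar's
#' association strength moves toward the signed reward side (+1 for right,
#' -1 for left) by `assoc_lr * (target - strength)`. Attention moves toward
#' the modality whose (pre-update) association sign already agreed with the
#' outcome when the other modality's disagreed, by `attn_lr`; the two
#' modality weights always sum to one. No-response trials leave the state
#' unchanged.
#'
#' @param state an [agent_state()].
#' @param trial a one-row trial record (needs `whisker_stim`, `odor_stim`,
#'   `rewarded_side`, `first_response`).
#' @return the updated `agent_state`.
#' @export
agent_update <- function(state, trial) {
  if (trial$first_response == "none") return(state)
  target <- if (trial$rewarded_side == "right") 1 else -1
  p <- state$params
  w <- trial$whisker_stim; o <- trial$odor_stim
  agree <- function(stim) {
    !is.na(stim) && sign(state$assoc[[stim]]) == sign(target)
  }
  w_agree <- agree(w); o_agree <- agree(o)
  if (!is.na(w)) {
    state$assoc[[w]] <- state$assoc[[w]] +
      p$assoc_lr * (target - state$assoc[[w]])
  }
  if (!is.na(o)) {
    state$assoc[[o]] <- state$assoc[[o]] +
      p$assoc_lr * (target - state$assoc[[o]])
  }
  state$assoc <- pmin(pmax(state$assoc, -1), 1)
  if (!is.na(w) && !is.na(o)) {
    if (w_agree && !o_agree) {
      state$attn_whisker <- state$attn_whisker +
        p$attn_lr * (1 - state$attn_whisker)
    } else if (o_agree && !w_agree) {
      state$attn_whisker <- state$attn_whisker * (1 - p$attn_lr)
    }
    state$attn_whisker <- min(1, max(0, state$attn_whisker))
  }
  state
}

#' A saturated, rule-following agent
#'
#' Convenience constructor for an agent whose associations already match the
#' given rule's latent maps at full strength and whose attention sits
#' entirely on the relevant modality — the idealized "expert" used to probe
#' congruency and perseveration signatures.
#'
#' @param rule a [rule_state()].
#' @param lapse lapse probability.
#' @param ... further overrides for [agent_params()].
#' @return an `agent_state`.
#' @export
saturated_agent <- function(rule, lapse = 0, ...) {
  sgn <- function(map) setNames(ifelse(map == "right", 1, -1), names(map))
  params <- agent_params(
    attn_whisker0 = if (rule$relevant_modality == "whisker") 1 else 0,
    inv_temp = 50, lapse = lapse, p_respond = 1,
    satiety_trials = 1e6, ...
  )
  agent_state(params,
              assoc = c(sgn(rule$whisker_map), sgn(rule$odor_map)))
}
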
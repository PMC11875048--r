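#' Pass-criterion specification
#'
#' Bundles the thresholds against which a session is judged: a moving-window
#' accuracy criterion, an optional minimum trial count, an optional
#' simultaneous left/right balance window, an optional response-rate floor,
#' and an optional consumed-volume target. The defaults correspond to the
#' discrimination-stage criterion: >100 trials, 80% accuracy in a 30-trial
#' moving window, both sides above 50% in a single 10-trial window, and a
#' response on more than 80% of trials.
#'
#' @param accuracy_threshold proportion correct required (inclusive).
#' @param accuracy_window moving-window length, in response trials.
#' @param min_trials minimum number of trials performed (strict >), or `NULL`.
#' @param side_balance `NULL`, or `list(threshold =, window =)`: a single
#'   window in which accuracy on left trials and on right trials must both
#'   strictly exceed the threshold.
#' @param response_rate_min minimum fraction of trials with a response
#'   (strict >), or `NULL`.
#' @param volume_target_ul consumed-volume pass target in microliters, or
#'   `NULL`.
#' @return a `criterion_spec` list.
#' @export
criterion_spec <- function(accuracy_threshold = 0.80, accuracy_window = 30L,
                           min_trials = 100L,
                           side_balance = list(threshold = 0.50, window = 10L),
                           response_rate_min = 0.80,
                           volume_target_ul = NULL) {
  if (!is.null(side_balance)) {
    side_balance <- list(threshold = as.numeric(side_balance$threshold),
                         window = as.integer(side_balance$window))
  }
  structure(
    list(
      accuracy_threshold = as.numeric(accuracy_threshold),
      accuracy_window = as.integer(accuracy_window),
      min_trials = if (!is.null(min_trials)) as.integer(min_trials),
      side_balance = side_balance,
      response_rate_min = if (!is.null(response_rate_min)) as.numeric(response_rate_min),
      volume_target_ul = if (!is.null(volume_target_ul)) as.numeric(volume_target_ul)
    ),
    class = "criterion_spec"
  )
}

#' Session configuration
#'
#' All timing, reward, criterion and randomization parameters for one
#' session. Defaults follow the task protocol: a 500 ms trial-start tone,
#' 2,500 ms stimulus epoch, 1,500 ms response window, 4 ul water droplets,
#' an 8,000-10,000 ms intertrial interval from simple discrimination onward
#' (3,000-4,500 ms during shaping), ~120 ms odorant command-to-nose latency,
#' and session termination after 10 consecutive no-response trials.
#'
#' @param stage_id stage token (`"HB1"`, ..., `"SH4"`, `"SH5"`, `"SD"`,
#'   `"CD"`, `"SEDS"`).
#' @param seed integer seed for the session.
#' @param tone_ms trial-onset tone duration.
#' @param stim_ms stimulus epoch duration.
#' @param response_window_ms response window duration.
#' @param iti_range_ms inclusive `[lo, hi]` intertrial-interval range.
#' @param habituation_timeout_range_ms post-reward timeout range used by the
#'   habituation stages.
#' @param droplet_ul water volume per reward.
#' @param odor_onset_latency_ms latency from odorant command to odorant at
#'   the nose.
#' @param odor_clear_ms passive odorant clearing time after stimulus offset
#'   (bookkeeping only).
#' @param bias_correction `list(enabled =, window =, clamp = c(pmin, pmax))`;
#'   when enabled, the reward side is drawn with probability of left equal to
#'   the clamped recent frequency of right responses.
#' @param no_response_termination consecutive no-response trials that end the
#'   session.
#' @param volume_pass_ul consumed volume that terminates (and passes) a
#'   habituation/shaping session, or `NULL`.
#' @param no_reward_timeout_ms end the session after this much simulated time
#'   without a reward (`NULL` to disable; used by HB1/HB2's two-minute rule).
#' @param criteria a [criterion_spec()] for stage evaluation.
#' @param hb3b_whisker_flash_ms range of the brief post-lick whisker flash in
#'   stage HB3B.
#' @param trial_cap hard cap on trials per session (guard, not protocol).
#' @return a `session_config` list.
#' @export
session_config <- function(stage_id = "SD",
                           seed = 1L,
                           tone_ms = 500L,
                           stim_ms = 2500L,
                           response_window_ms = 1500L,
                           iti_range_ms = c(8000L, 10000L),
                           habituation_timeout_range_ms = c(500L, 1500L),
                           droplet_ul = 4,
                           odor_onset_latency_ms = 120L,
                           odor_clear_ms = 2000L,
                           bias_correction = list(enabled = FALSE, window = 20L,
                                                  clamp = c(0.1, 0.9)),
                           no_response_termination = 10L,
                           volume_pass_ul = NULL,
                           no_reward_timeout_ms = NULL,
                           criteria = criterion_spec(),
                           hb3b_whisker_flash_ms = c(150L, 300L),
                           trial_cap = 2000L) {
  structure(
    list(
      stage_id = stage_id, seed = as.integer(seed),
      tone_ms = as.integer(tone_ms), stim_ms = as.integer(stim_ms),
      response_window_ms = as.integer(response_window_ms),
      iti_range_ms = as.integer(iti_range_ms),
      habituation_timeout_range_ms = as.integer(habituation_timeout_range_ms),
      droplet_ul = as.numeric(droplet_ul),
      odor_onset_latency_ms = as.integer(odor_onset_latency_ms),
      odor_clear_ms = as.integer(odor_clear_ms),
      bias_correction = list(enabled = isTRUE(bias_correction$enabled),
                             window = as.integer(bias_correction$window),
                             clamp = as.numeric(bias_correction$clamp)),
      no_response_termination = as.integer(no_response_termination),
      volume_pass_ul = if (!is.null(volume_pass_ul)) as.numeric(volume_pass_ul),
      no_reward_timeout_ms = if (!is.null(no_reward_timeout_ms)) as.integer(no_reward_timeout_ms),
      criteria = criteria,
      hb3b_whisker_flash_ms = as.integer(hb3b_whisker_flash_ms),
      trial_cap = as.integer(trial_cap)
    ),
    class = "session_config"
  )
}

#' Stage-preset session configuration
#'
#' Returns [session_config()] preset for a named curriculum stage:
#' habituation stages use the 0.5-1.5 s post-reward timeout and the 500 ul
#' volume target; shaping stages use the 3,000-4,500 ms intertrial interval;
#' simple discrimination and later use 8,000-10,000 ms and the fourfold
#' discrimination criterion.
#'
#' @param stage_id one of HB1, HB2, HB3, HB3B, SH4, SH5, SD, CD, SEDS.
#' @param seed session seed.
#' @param ... overrides passed on to [session_config()].
#' @export
stage_config <- function(stage_id, seed = 1L, ...) {
  base <- switch(stage_id,
    HB1 = ,
    HB2 = list(tone_ms = 0L, stim_ms = 0L,
               iti_range_ms = c(500L, 1500L),
               volume_pass_ul = 500, no_reward_timeout_ms = 120000L,
               criteria = criterion_spec(accuracy_threshold = 1,
                                         accuracy_window = 1L,
                                         min_trials = NULL, side_balance = NULL,
                                         response_rate_min = NULL,
                                         volume_target_ul = 500)),
    HB3 = ,
    HB3B = list(tone_ms = 0L, stim_ms = 0L,
                iti_range_ms = c(500L, 1500L),
                volume_pass_ul = 500,
                criteria = criterion_spec(accuracy_threshold = 1,
                                          accuracy_window = 1L,
                                          min_trials = NULL,
                                          side_balance = NULL,
                                          response_rate_min = NULL,
                                          volume_target_ul = 500)),
    SH4 = list(iti_range_ms = c(3000L, 4500L), volume_pass_ul = 500,
               criteria = criterion_spec(accuracy_threshold = 1,
                                         accuracy_window = 1L,
                                         min_trials = NULL, side_balance = NULL,
                                         response_rate_min = NULL,
                                         volume_target_ul = 500)),
    SH5 = list(iti_range_ms = c(3000L, 4500L),
               criteria = criterion_spec(accuracy_threshold = 0.80,
                                         accuracy_window = 100L,
                                         min_trials = NULL, side_balance = NULL,
                                         response_rate_min = NULL)),
    SD = ,
    CD = list(criteria = criterion_spec()),
    SEDS = list(bias_correction = list(enabled = TRUE, window = 20L,
                                       clamp = c(0.1, 0.9)),
                criteria = criterion_spec()),
    abort(paste0("unknown stage '", stage_id, "'"))
  )
  do.call(session_config,
          modifyList(c(list(stage_id = stage_id, seed = seed), base),
                     list(...)))
}

#' Validate a session configuration
#'
#' Checks every bound the configuration must satisfy and returns a character
#' vector of violations (empty when valid); violations name the offending
#' field. Nothing is raised, so the result can drive a config linter.
#'
#' @param config a [session_config()].
#' @return character vector of violation descriptions.
#' @export
validate_config <- function(config) {
  v <- character()
  pos <- function(field) {
    if (any(config[[field]] <= 0)) {
      v <<- c(v, paste0(field, ": must be positive"))
    }
  }
  for (f in c("tone_ms", "stim_ms", "response_window_ms")) {
    if (config[[f]] < 0) v <- c(v, paste0(f, ": must be nonnegative"))
  }
  pos("response_window_ms")
  for (f in c("iti_range_ms", "habituation_timeout_range_ms",
              "hb3b_whisker_flash_ms")) {
    r <- config[[f]]
    if (length(r) != 2) {
      v <- c(v, paste0(f, ": must be a [lo, hi] pair"))
    } else {
      if (any(r <= 0)) v <- c(v, paste0(f, ": durations must be positive"))
      if (r[1] > r[2]) v <- c(v, paste0(f, ": lo exceeds hi"))
    }
  }
  if (config$droplet_ul <= 0) v <- c(v, "droplet_ul: must be positive")
  if (config$odor_onset_latency_ms < 0) {
    v <- c(v, "odor_onset_latency_ms: must be nonnegative")
  }
  bc <- config$bias_correction
  if (!is.null(bc$clamp)) {
    pmin <- bc$clamp[1]; pmax <- bc$clamp[2]
    if (!(pmin > 0)) v <- c(v, "bias_correction clamp: pmin must exceed 0")
    if (!(pmin <= 0.5)) v <- c(v, "bias_correction clamp: pmin must not exceed 0.5")
    if (!(pmax >= 0.5)) v <- c(v, "bias_correction clamp: pmax must be at least 0.5")
    if (!(pmax < 1)) v <- c(v, "bias_correction clamp: pmax must be below 1")
  }
  if (!is.null(bc$window) && bc$window < 1) {
    v <- c(v, "bias_correction window: must be >= 1")
  }
  if (config$no_response_termination < 1) {
    v <- c(v, "no_response_termination: must be >= 1")
  }
  if (config$trial_cap < 1) v <- c(v, "trial_cap: must be >= 1")
  cr <- config$criteria
  if (!(cr$accuracy_threshold > 0 && cr$accuracy_threshold <= 1)) {
    v <- c(v, "criteria accuracy_threshold: must lie in (0, 1]")
  }
  if (cr$accuracy_window < 1) v <- c(v, "criteria accuracy_window: must be >= 1")
  if (!is.null(cr$side_balance) && cr$side_balance$window < 1) {
    v <- c(v, "criteria side_balance window: must be >= 1")
  }
  v
}

config_field_names <- function() {
  names(session_config())
}

#' Write / read a session configuration file
#'
#' Configurations are stored as YAML, one document per session, mirroring the
#' fields of [session_config()]. Unknown keys in a file are an error, so
#' typos do not silently fall back to defaults.
#'
#' @param config a [session_config()].
#' @param path file path.
#' @return `write_config` returns `path` invisibly; `read_config` returns the
#'   `session_config`.
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  x$criteria <- unclass(x$criteria)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  known <- config_field_names()
  unknown <- setdiff(names(x), known)
  if (length(unknown)) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  if (!is.null(x$criteria)) x$criteria <- do.call(criterion_spec, x$criteria)
  cfg <- do.call(session_config, x)
  # YAML loses NULL-vs-missing distinctions; rebuild through the constructor
  cfg
}
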
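test_that("reward semantics differ between shaping stages", {
  licks <- list(t_ms = c(100L, 300L), side = c("right", "left"))
  # permissive: a wrong lick before the correct one still earns reward
  sh4 <- apply_reward_rule("SH4", licks, "left")
  expect_true(sh4$rewarded)
  expect_identical(sh4$first_response, "right")
  expect_false(sh4$correct)
  expect_equal(sh4$reward_t_ms, 300L)
  # strict: the first lick must be correct
  sh5 <- apply_reward_rule("SH5", licks, "left")
  expect_false(sh5$rewarded)
  expect_identical(sh5$first_response, "right")
  expect_false(sh5$correct)
  # omission
  om <- apply_reward_rule("SD", list(t_ms = integer(0), side = character(0)),
                          "left")
  expect_identical(om$first_response, "none")
  expect_true(is.na(om$correct))
  expect_false(om$rewarded)
  expect_error(apply_reward_rule("XX", licks, "left"), "XX")
})

test_that("trial event schedule matches the task timing", {
  # tone 0-500 ms, stimulus 500-3000 ms, response window opens 2500 ms after
  # stimulus onset and lasts 1500 ms
  cfg <- stage_config("SD", seed = 5)
  rule <- rule_state()
  ag <- saturated_agent(rule)
  ag <- agent_rest(ag)
  withr::with_seed(5, {
    res <- run_trial(list(whisker_stim = "W1", odor_stim = NA,
                          rewarded_side = "left"),
                     rule, ag, cfg, t0 = 0L, trial_index = 1L)
  })
  ev <- res$events
  at <- function(kind) ev$t_ms[ev$kind == kind]
  expect_equal(at("trial_start"), 0L)
  expect_equal(at("tone_on"), 0L)
  expect_equal(at("tone_off"), 500L)
  expect_equal(at("whisker_on"), 500L)              # stimulus at tone offset
  expect_equal(at("response_window_on") - at("whisker_on"), 2500L)
  expect_equal(res$trial$first_response, "left")
  expect_true(res$trial$rewarded)
})

test_that("odorant command-to-nose latency is honored", {
  cfg <- stage_config("SEDS", seed = 5)
  rule <- rule_state()
  ag <- agent_rest(saturated_agent(rule))
  withr::with_seed(5, {
    res <- run_trial(list(whisker_stim = "W1", odor_stim = "O1",
                          rewarded_side = "left"),
                     rule, ag, cfg)
  })
  ev <- res$events
  expect_equal(ev$t_ms[ev$kind == "odor_nose_on"] -
                 ev$t_ms[ev$kind == "odor_command_on"],
               cfg$odor_onset_latency_ms)
})

test_that("a non-responding agent yields an omission and no reward", {
  cfg <- stage_config("SD", seed = 9)
  rule <- rule_state()
  ag <- agent_state(agent_params(p_respond = 1e-12))
  ag <- agent_rest(ag)
  withr::with_seed(9, {
    res <- run_trial(list(whisker_stim = "W1", odor_stim = NA,
                          rewarded_side = "left"), rule, ag, cfg)
  })
  expect_identical(res$trial$first_response, "none")
  expect_false(res$trial$rewarded)
  expect_true("omission" %in% res$events$kind)
  expect_equal(res$trial$reward_volume_ul, 0)
})

test_that("a satiated agent is refused", {
  ag <- agent_state()
  ag$satiated <- TRUE
  expect_error(run_trial(list(whisker_stim = "W1", odor_stim = NA,
                              rewarded_side = "left"),
                         rule_state(), ag, stage_config("SD")),
               "satiated")
})

test_that("sessions terminate after the configured run of no-responses", {
  cfg <- stage_config("SD", seed = 3)
  ag <- agent_state(agent_params(p_respond = 1e-12))
  log <- run_session(cfg, rule_state(), ag)
  expect_equal(nrow(log$trials), 10L)
  expect_identical(log$terminated_by, "no_response_run")
  expect_true(all(log$trials$first_response == "none"))
  expect_true(log$final_agent$satiated)
})

test_that("trial cap bounds a session", {
  cfg <- stage_config("SD", seed = 3, trial_cap = 1L)
  log <- run_session(cfg, rule_state(), agent_state())
  expect_equal(nrow(log$trials), 1L)
  expect_identical(log$terminated_by, "trial_cap")
})

test_that("identical seeds give identical session logs", {
  a <- run_seds_session(stage_config("SEDS", seed = 11), rule_state(),
                        agent_state())
  b <- run_seds_session(stage_config("SEDS", seed = 11), rule_state(),
                        agent_state())
  expect_equal(a$trials, b$trials)
  expect_equal(a$events, b$events)
  expect_equal(a$shifts, b$shifts)
})

test_that("every emitted record passes the shared invariant validator", {
  for (stage in c("HB1", "HB3B", "SH4", "SD")) {
    log <- run_session(stage_config(stage, seed = 21, trial_cap = 150L),
                       rule_state(), agent_state())
    validate_session_log(log)
  }
  log <- run_seds_session(stage_config("SEDS", seed = 21, trial_cap = 150L),
                          rule_state(), agent_state())
  validate_session_log(log)
  # intertrial spacing: consecutive trial starts at least iti lo apart
  expect_true(all(diff(log$trials$t_start_ms) >= log$config$iti_range_ms[1]))
})

test_that("pulse trains have exact period and truncation", {
  tr <- schedule_pulse_train(10, 1000, 5)
  expect_equal(tr$ttl_pulse_on, seq(0L, 900L, by = 100L))
  expect_equal(tr$ttl_pulse_off - tr$ttl_pulse_on, rep(5L, 10))
  expect_equal(nrow(schedule_pulse_train(1, 500, 5)), 1L)
  expect_equal(schedule_pulse_train(1, 500, 5)$ttl_pulse_on, 0L)
  expect_error(schedule_pulse_train(10, 1000, 150), "period")
})
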
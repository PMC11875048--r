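test_that("choice probabilities follow the lapse-mixture logistic", {
  withr::local_seed(42)
  # saturated evidence, no lapse: deterministic choice
  ag <- agent_state(agent_params(attn_whisker0 = 1, inv_temp = 50, lapse = 0,
                                 p_respond = 1),
                    assoc = c(W1 = -1))
  ag <- agent_rest(ag)
  sides <- replicate(200, agent_choose(ag, "W1", NA)$response)
  expect_true(all(sides == "left"))

  # pure lapse: a fair coin
  ag <- agent_rest(agent_state(agent_params(lapse = 1, p_respond = 1)))
  sides <- replicate(5000, agent_choose(ag, "W1", NA)$response)
  expect_lt(abs(mean(sides == "right") - 0.5), 3 * sqrt(0.25 / 5000))

  # closed-form mixture: lapse 0.2, inv_temp 2, evidence +1
  ag <- agent_rest(agent_state(agent_params(attn_whisker0 = 1, inv_temp = 2,
                                            lapse = 0.2, p_respond = 1),
                               assoc = c(W1 = 1)))
  p_true <- 0.2 * 0.5 + 0.8 * plogis(2)
  sides <- replicate(8000, agent_choose(ag, "W1", NA)$response)
  expect_lt(abs(mean(sides == "right") - p_true),
            3 * sqrt(p_true * (1 - p_true) / 8000))
})

test_that("attention renormalizes over the presented stimuli", {
  ag <- agent_state(agent_params(attn_whisker0 = 0.25),
                    assoc = c(W1 = 1, O1 = -1))
  # both stimuli: weighted sum
  expect_equal(setshiftr:::agent_evidence(0.25, ag$assoc, "W1", "O1"),
               0.25 * 1 + 0.75 * -1)
  # single stimulus: its weight renormalizes to 1
  expect_equal(setshiftr:::agent_evidence(0.25, ag$assoc, "W1", NA), 1)
  expect_equal(setshiftr:::agent_evidence(0.25, ag$assoc, NA, "O1"), -1)
})

test_that("associations converge monotonically under consistent reward", {
  ag <- agent_state(agent_params(assoc_lr = 0.3))
  trial <- tibble::tibble(whisker_stim = "W1", odor_stim = NA_character_,
                          rewarded_side = "left", first_response = "left")
  prev <- 0
  for (i in 1:25) {
    ag <- agent_update(ag, trial)
    expect_lte(ag$assoc[["W1"]], prev)
    prev <- ag$assoc[["W1"]]
    expect_gte(prev, -1)
  }
  expect_lt(prev, -0.999)
})

test_that("zero learning rates leave the agent unchanged", {
  ag <- agent_state(agent_params(assoc_lr = 0, attn_lr = 0),
                    assoc = c(W1 = 0.4, O1 = -0.2))
  trial <- tibble::tibble(whisker_stim = "W1", odor_stim = "O1",
                          rewarded_side = "right", first_response = "right")
  ag2 <- agent_update(ag, trial)
  expect_identical(ag2$assoc, ag$assoc)
  expect_identical(ag2$attn_whisker, ag$attn_whisker)
  # and a no-response trial is always an identity
  ag3 <- agent_update(agent_state(),
                      tibble::tibble(whisker_stim = "W1",
                                     odor_stim = NA_character_,
                                     rewarded_side = "left",
                                     first_response = "none"))
  expect_identical(ag3$assoc, agent_state()$assoc)
})

test_that("anticipatory lick trains run at the configured rate", {
  withr::local_seed(3)
  isis <- c()
  ag <- agent_rest(agent_state(agent_params(p_respond = 1)))
  for (i in 1:100) {
    ch <- agent_choose(ag, "W1", NA)
    isis <- c(isis, diff(ch$lick_times))
  }
  expect_lt(abs(mean(isis) - 125), 12.5)  # 8 Hz +/- 10%
})

test_that("cohorts are reproducible and moderate learners switch rules", {
  co1 <- generate_cohort(2, sessions_per_agent = 1, seed = 6,
                         config = stage_config("SEDS", trial_cap = 300L))
  co2 <- generate_cohort(2, sessions_per_agent = 1, seed = 6,
                         config = stage_config("SEDS", trial_cap = 300L))
  expect_equal(co1[[1]]$params, co2[[1]]$params)
  expect_equal(co1[[1]]$logs[[1]]$trials, co2[[1]]$logs[[1]]$trials)
  expect_equal(co1[[2]]$logs[[1]]$events, co2[[2]]$logs[[1]]$events)
  for (a in co1) {
    expect_gte(nrow(a$logs[[1]]$shifts), 1)
  }
})

test_that("a degenerate perfect cohort switches every 30 response trials", {
  rule <- rule_state()
  perfect <- list(attn_whisker0 = c(1, 1), assoc_lr = c(1, 1),
                  attn_lr = c(0, 0), inv_temp = c(50, 50), lapse = c(0, 0),
                  side_bias = c(0, 0), p_respond = c(1, 1),
                  satiety_trials = c(1e6, 1e6))
  cfg <- stage_config("SEDS", trial_cap = 95L)
  co <- generate_cohort(1, param_ranges = perfect, seed = 9, config = cfg,
                        shift_sequence = "Rev")
  # reversals relearned instantly at lr 1 with full information: the
  # trigger arithmetic makes every block exactly 30 response trials
  log <- co[[1]]$logs[[1]]
  expect_equal(log$shifts$trial_index, c(30L, 60L, 90L))
})

test_that("grid fits recover the generating parameters' neighborhood", {
  # singleton grid returns that point; degenerate inputs error
  logs <- list(run_seds_session(stage_config("SEDS", seed = 17, trial_cap = 600L),
                                rule_state(),
                                agent_state(agent_params(satiety_trials = 1e6))))
  g1 <- fit_agent(logs, list(lapse = 0.1, attn_whisker0 = 0.5, inv_temp = 3))
  expect_equal(nrow(g1$grid), 1L)
  expect_equal(g1$best$lapse, 0.1)
  expect_error(fit_agent(logs, list()), "grid")
  short <- list(make_log(random_outcome_trials(20)))
  expect_error(fit_agent(short,
                         list(lapse = 0.1, attn_whisker0 = 0.5, inv_temp = 3)),
               "500")
})
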
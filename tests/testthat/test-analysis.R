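test_that("moving accuracy matches the brute-force scan", {
  withr::local_seed(55)
  # all correct: constant 1 from the first full window
  tr <- random_outcome_trials(40, p_none = 0, p_correct = 1)
  acc <- moving_accuracy(tr, 20)$accuracy
  expect_true(all(is.na(acc[1:19])))
  expect_true(all(acc[20:40] == 1))
  # too short: never a full window
  tr <- random_outcome_trials(19, p_none = 0)
  expect_true(all(is.na(moving_accuracy(tr, 20)$accuracy)))
  # random sequences: exact oracle equivalence
  for (rep in 1:100) {
    n <- sample(5:200, 1)
    w <- sample(c(5L, 10L, 20L, 30L), 1)
    tr <- random_outcome_trials(n, p_none = runif(1, 0, 0.3),
                                p_correct = runif(1, 0.3, 0.95))
    expect_identical(moving_accuracy(tr, w)$accuracy,
                     brute_moving_accuracy(tr, w))
  }
})

test_that("trials to criterion matches the brute-force scan", {
  withr::local_seed(56)
  cr <- criterion_spec(accuracy_window = 20L, min_trials = NULL,
                       side_balance = NULL, response_rate_min = NULL)
  tr <- random_outcome_trials(20, p_none = 0, p_correct = 1)
  expect_identical(trials_to_criterion(tr, cr), 20L)  # earliest possible
  alt <- random_outcome_trials(40, p_none = 0)
  alt$correct <- rep(c(TRUE, FALSE), 20)
  alt$first_response <- ifelse(alt$correct, alt$rewarded_side,
                               ifelse(alt$rewarded_side == "left", "right",
                                      "left"))
  expect_true(is.na(trials_to_criterion(alt, cr)))    # pinned at 50%
  for (rep in 1:100) {
    n <- sample(5:200, 1)
    w <- sample(c(10L, 20L, 30L), 1)
    tr <- random_outcome_trials(n, p_none = runif(1, 0, 0.3),
                                p_correct = runif(1, 0.3, 0.95))
    crw <- criterion_spec(accuracy_window = w, min_trials = NULL,
                          side_balance = NULL, response_rate_min = NULL)
    expect_identical(trials_to_criterion(tr, crw),
                     brute_ttc(tr, w, 0.8))
  }
})

test_that("block segmentation splits at switch indices", {
  withr::local_seed(57)
  tr <- random_outcome_trials(120)
  # no switches: one open block
  b0 <- segment_blocks(tr)
  expect_equal(nrow(b0), 1L)
  expect_equal(b0$n_trials, 120L)
  expect_identical(b0$ended_by, "open")
  # switches after trials 40 and 90
  sw <- tibble::tibble(trial_index = c(40L, 90L),
                       shift_type = c("EDS", "EDS"))
  b <- segment_blocks(tr, sw)
  expect_equal(b$n_trials, c(40L, 50L, 30L))
  expect_equal(b$start, c(1L, 41L, 91L))
  expect_identical(b$ended_by, c("EDS", "EDS", "open"))
  # malformed switch index
  expect_error(segment_blocks(tr, tibble::tibble(trial_index = 0L,
                                                 shift_type = "EDS")),
               "nonexistent")
})

test_that("switch alignment labels offsets and cells correctly", {
  withr::local_seed(58)
  tr <- random_outcome_trials(60, p_none = 0, p_correct = 1)
  tr$congruent <- rep(c(TRUE, FALSE), 30)
  sw <- tibble::tibble(trial_index = 30L, shift_type = "EDS")
  lab <- periswitch_trials(tr, sw)
  expect_equal(range(lab$offset), c(-10L, 9L))
  expect_identical(lab$timing[lab$offset < 0], rep("pre", 10))
  expect_identical(lab$timing[lab$offset >= 0], rep("post", 10))
  expect_equal(lab$trial_index[lab$offset == 0], 31L)
  # all-correct log: every cell mean is 1
  log <- make_log(tr)
  log$shifts <- sw
  sa <- switch_aligned(log)
  expect_true(all(sa$cells$mean_accuracy == 1))
  expect_equal(sum(sa$cells$n), 20L)
  # no switches: error
  expect_error(switch_aligned(make_log(tr)), "no rule switches")
})

test_that("the factorial ANOVA reproduces a hand-computed balanced table", {
  # balanced 2x2x2, n = 2 per cell; sums of squares computed from cell
  # means with the classical balanced formulas
  d <- expand.grid(modality = c("whisker", "odor"),
                   congruency = c("congruent", "incongruent"),
                   timing = c("pre", "post"),
                   rep = 1:2, stringsAsFactors = FALSE)
  d$correct <- c(1, 1, 1, 0, 1, 0, 0, 0,
                 1, 1, 0, 0, 1, 1, 0, 1)
  an <- periswitch_anova(d)

  y <- d$correct
  n <- length(y)
  gm <- mean(y)
  ss_factor <- function(f) {
    m <- tapply(y, d[[f]], mean)
    sum(table(d[[f]]) * (m - gm)^2)
  }
  ss_inter <- function(f1, f2) {
    mm <- tapply(y, list(d[[f1]], d[[f2]]), mean)
    m1 <- tapply(y, d[[f1]], mean)
    m2 <- tapply(y, d[[f2]], mean)
    tot <- 0
    for (a in rownames(mm)) {
      for (b in colnames(mm)) {
        tot <- tot + 4 * (mm[a, b] - m1[a] - m2[b] + gm)^2
      }
    }
    unname(tot)
  }
  expect_equal(an$sumsq[an$effect == "modality"], ss_factor("modality"),
               tolerance = 1e-6)
  expect_equal(an$sumsq[an$effect == "congruency"], ss_factor("congruency"),
               tolerance = 1e-6)
  expect_equal(an$sumsq[an$effect == "timing"], ss_factor("timing"),
               tolerance = 1e-6)
  expect_equal(an$sumsq[an$effect == "modality:congruency"],
               ss_inter("modality", "congruency"), tolerance = 1e-6)
  expect_equal(an$sumsq[an$effect == "congruency:timing"],
               ss_inter("congruency", "timing"), tolerance = 1e-6)
  # F ratios follow from the residual mean square
  ss_res <- an$sumsq[an$effect == "residuals"]
  df_res <- an$df[an$effect == "residuals"]
  expect_equal(an$statistic[an$effect == "congruency"],
               ss_factor("congruency") / (ss_res / df_res), tolerance = 1e-6)
  expect_true(all(an$statistic[!is.na(an$statistic)] >= 0))
})

test_that("sequential and marginal ANOVA agree on balanced data", {
  d <- expand.grid(modality = c("whisker", "odor"),
                   congruency = c("congruent", "incongruent"),
                   timing = c("pre", "post"),
                   rep = 1:5, stringsAsFactors = FALSE)
  withr::local_seed(1)
  d$correct <- as.numeric(runif(nrow(d)) < 0.7)
  a3 <- periswitch_anova(d, type = "III")
  a1 <- periswitch_anova(d, type = "I")
  expect_equal(a3$sumsq[match(a1$effect, a3$effect)], a1$sumsq,
               tolerance = 1e-10)
})

test_that("the ANOVA refuses a single-level factor", {
  d <- expand.grid(modality = "whisker",
                   congruency = c("congruent", "incongruent"),
                   timing = c("pre", "post"), rep = 1:3,
                   stringsAsFactors = FALSE)
  d$correct <- 1
  expect_error(periswitch_anova(d), "modality")
})

test_that("lick histograms conserve counts and recover the lick rate", {
  # constructed 8 Hz train through the stimulus epoch of each of 50 trials
  ev <- list()
  for (i in 1:50) {
    t0 <- (i - 1L) * 10000L
    lick_t <- t0 + seq(63L, 2438L, by = 125L)  # 20 licks at 8 Hz
    ev[[i]] <- tibble::tibble(
      t_ms = c(t0 + 2500L, lick_t),
      trial_index = i,
      kind = c("response_window_on", rep("lick_left", length(lick_t))),
      side = c(NA, rep("left", length(lick_t))))
  }
  ev <- dplyr::bind_rows(ev)
  psth <- lick_psth(ev, bin_ms = 250L, window = c(-2500L, 0L))
  left <- psth[psth$side == "left", ]
  expect_equal(sum(psth$count), 50L * 20L)  # conservation
  expect_true(all(abs(left$rate_hz - 8) < 1e-9))
  expect_true(all(psth$count[psth$side == "right"] == 0))
  # no licks at all: all-zero histogram
  anchors_only <- ev[ev$kind == "response_window_on", ]
  z <- lick_psth(anchors_only, bin_ms = 250L, window = c(-2500L, 0L))
  expect_true(all(z$count == 0))
  expect_error(lick_psth(ev, align_to = "tone_on"), "tone_on")
})

test_that("session summaries report exact counts", {
  expect_equal(nrow(session_summary(list())), 0L)
  logs <- lapply(1:3, function(s) {
    run_seds_session(stage_config("SEDS", seed = 200 + s, trial_cap = 120L),
                     rule_state(), agent_state())
  })
  sm <- session_summary(logs)
  expect_equal(nrow(sm), 3L)
  for (i in 1:3) {
    expect_equal(sm$n_trials[i], nrow(logs[[i]]$trials))
    expect_equal(sm$n_switches[i], nrow(logs[[i]]$shifts))
    expect_equal(sm$total_volume_ul[i],
                 sum(logs[[i]]$trials$reward_volume_ul))
  }
  # analyses are pure: identical inputs give identical outputs
  expect_identical(session_summary(logs), session_summary(logs))
  expect_identical(moving_accuracy(logs[[1]]$trials, 20),
                   moving_accuracy(logs[[1]]$trials, 20))
})
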
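#' Default cohort parameter ranges
#'
#' Uniform ranges from which cohort agents' parameters are drawn. Chosen so
#' that simulated set-shifting sessions land in a realistic envelope of a
#' few hundred trials per session with several rule switches each.
#'
#' @return named list of `[lo, hi]` ranges.
#' @export
cohort_param_ranges <- function() {
  list(attn_whisker0 = c(0.3, 0.7), assoc_lr = c(0.1, 0.3),
       attn_lr = c(0.05, 0.2), inv_temp = c(2, 5), lapse = c(0.05, 0.15),
       side_bias = c(-0.5, 0.5), p_respond = c(0.9, 1),
       satiety_trials = c(350, 550))
}

#' Simulate a cohort of agents on the set-shifting task
#'
#' Draws each agent's parameters uniformly from the given ranges using the
#' cohort seed, runs serial set-shifting sessions (associations carried
#' across an agent's sessions), and returns all logs. Fully reproducible
#' from the seed.
#'
#' @param n_agents number of agents.
#' @param param_ranges per-parameter `[lo, hi]` ranges (see
#'   [cohort_param_ranges()]).
#' @param sessions_per_agent sessions per agent.
#' @param seed cohort seed.
#' @param config a [session_config()] template (stage `"SEDS"`).
#' @param rule initial [rule_state()].
#' @param shift_sequence shift types, recycled (default alternating EDS).
#' @return a `cohort`: list of `list(params, logs)` per agent.
#' @export
generate_cohort <- function(n_agents, param_ranges = cohort_param_ranges(),
                            sessions_per_agent = 1L, seed = 1L,
                            config = stage_config("SEDS"),
                            rule = rule_state(),
                            shift_sequence = "EDS") {
  stopifnot(n_agents >= 1)
  draw <- function(r) runif(1, r[1], r[2])
  agents <- withr::with_seed(derive_seed(seed, 0L), {
    lapply(seq_len(n_agents), function(i) {
      do.call(agent_params, lapply(param_ranges, draw))
    })
  })
  out <- vector("list", n_agents)
  for (i in seq_len(n_agents)) {
    ag <- agent_state(agents[[i]])
    logs <- vector("list", sessions_per_agent)
    aseed <- derive_seed(seed, i)
    for (s in seq_len(sessions_per_agent)) {
      cfg <- config
      cfg$seed <- derive_seed(aseed, s)
      log <- run_seds_session(cfg, rule, ag, shift_sequence)
      ag <- log$final_agent
      logs[[s]] <- log
    }
    out[[i]] <- list(params = agents[[i]], logs = logs)
  }
  structure(out, class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  n_sess <- sum(vapply(x, function(a) length(a$logs), 1L))
  cat("<cohort>", length(x), "agents,", n_sess, "sessions\n")
  invisible(x)
}

# Deterministic replay of the learning trajectory through logged trials:
# returns the pre-choice evidence for every response trial, in order.
replay_evidence <- function(logs, params) {
  state <- agent_state(params)
  ev <- numeric(0)
  y <- integer(0)
  for (log in logs) {
    tr <- log$trials
    resp <- tr$first_response != "none"
    evs <- numeric(sum(resp))
    k <- 0L
    for (i in seq_len(nrow(tr))) {
      if (!resp[i]) next
      k <- k + 1L
      evs[k] <- agent_evidence(state$attn_whisker, state$assoc,
                               tr$whisker_stim[i], tr$odor_stim[i])
      state <- agent_update(state, tr[i, ])
    }
    ev <- c(ev, evs)
    y <- c(y, as.integer(tr$first_response[resp] == "right"))
  }
  list(evidence = ev, y = y)
}

#' Fit agent parameters to logged sessions by grid search
#'
#' Maximizes the Bernoulli log-likelihood of the observed left/right
#' responses over a grid of `lapse`, `attn_whisker0` and `inv_temp`. For
#' each candidate initial attention weight the learning trajectory is
#' replayed deterministically from the logged trials (stimuli, rewarded
#' sides and responses), giving the per-trial choice evidence; the choice
#' probability is then the lapse-mixture logistic
#' `lapse/2 + (1 - lapse) * plogis(inv_temp * evidence + side_bias)`.
#'
#' @param logs a `session_log` or list of them (>= 500 response trials).
#' @param grid named list with numeric vectors `lapse`, `attn_whisker0`,
#'   `inv_temp`; their Cartesian product is searched.
#' @param known an [agent_params()] supplying the non-fitted parameters
#'   (`assoc_lr`, `attn_lr`, `side_bias`).
#' @return an `agent_fit`: list with `best` (one-row tibble), `grid` (all
#'   grid points with log-likelihoods), `n_response_trials`.
#' @export
fit_agent <- function(logs, grid, known = agent_params()) {
  if (inherits(logs, "session_log")) logs <- list(logs)
  if (!length(grid) || any(lengths(grid) == 0) ||
      !all(c("lapse", "attn_whisker0", "inv_temp") %in% names(grid))) {
    abort("grid must supply nonempty lapse, attn_whisker0 and inv_temp values")
  }
  n_resp <- sum(vapply(logs, function(l) {
    sum(l$trials$first_response != "none")
  }, 1L))
  if (n_resp < 500) {
    abort(paste0("need at least 500 response trials to fit; have ", n_resp))
  }
  rows <- list()
  for (a0 in grid$attn_whisker0) {
    p <- known
    p$attn_whisker0 <- a0
    rp <- replay_evidence(logs, p)
    for (lt in grid$inv_temp) {
      base <- plogis(lt * rp$evidence + known$side_bias)
      for (lp in grid$lapse) {
        pr <- lp / 2 + (1 - lp) * base
        pr <- pmin(1 - 1e-12, pmax(1e-12, pr))
        ll <- sum(rp$y * log(pr) + (1 - rp$y) * log(1 - pr))
        rows[[length(rows) + 1L]] <- tibble(
          lapse = lp, attn_whisker0 = a0, inv_temp = lt, logLik = ll)
      }
    }
  }
  g <- dplyr::bind_rows(rows)
  best <- g[which.max(g$logLik), ]
  structure(list(best = best, grid = g, n_response_trials = n_resp),
            class = "agent_fit")
}

#' @export
print.agent_fit <- function(x, ...) {
  cat("<agent_fit> over", nrow(x$grid), "grid points,",
      x$n_response_trials, "response trials\n")
  print(x$best)
  invisible(x)
}

#' Tidy an agent fit (the full likelihood grid)
#'
#' @param x an `agent_fit`.
#' @param ... unused.
#' @export
tidy.agent_fit <- function(x, ...) x$grid

#' One-row best-fit summary of an agent fit
#'
#' @param x an `agent_fit`.
#' @param ... unused.
#' @export
glance.agent_fit <- function(x, ...) {
  dplyr::bind_cols(x$best, tibble(n_response_trials = x$n_response_trials))
}
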
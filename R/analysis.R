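#' Moving-window response accuracy
#'
#' For each trial, the fraction correct among the trailing `window` response
#' trials up to and including it; `NA` until the first full window.
#' No-response trials never enter the numerator or denominator but keep
#' their row (carrying the accuracy of the trailing window ending at or
#' before them).
#'
#' @param trials trial tibble (needs `first_response`, `correct`).
#' @param window window length in response trials.
#' @return tibble `(trial_index, accuracy)`, one row per input trial.
#' @export
moving_accuracy <- function(trials, window = 20L) {
  stopifnot(window >= 1)
  n <- nrow(trials)
  resp <- trials$first_response != "none"
  cc <- trials$correct[resp]
  cs <- c(0, cumsum(cc))
  # k[i] = number of response trials among trials 1..i
  k <- cumsum(resp)
  acc <- rep(NA_real_, n)
  ok <- k >= window
  acc[ok] <- (cs[k[ok] + 1L] - cs[k[ok] - window + 1L]) / window
  tibble(trial_index = trials$trial_index %||% seq_len(n), accuracy = acc)
}

#' Trials to criterion
#'
#' The 1-based index, counted in response trials from block start, of the
#' first trial at which the criterion's trailing accuracy window is
#' satisfied; `NA` if never reached.
#'
#' @param trials trial tibble for one block.
#' @param criterion a [criterion_spec()]; only its accuracy window and
#'   threshold are used here.
#' @return integer or `NA` (not reached).
#' @export
trials_to_criterion <- function(trials,
                                criterion = criterion_spec(
                                  accuracy_window = 20L, min_trials = NULL,
                                  side_balance = NULL,
                                  response_rate_min = NULL)) {
  cc <- trials$correct[trials$first_response != "none"]
  n <- length(cc)
  w <- criterion$accuracy_window
  if (n < w) return(NA_integer_)
  cs <- c(0, cumsum(cc))
  ks <- w:n
  acc <- (cs[ks + 1L] - cs[ks - w + 1L]) / w
  hit <- which(acc >= criterion$accuracy_threshold)
  if (!length(hit)) return(NA_integer_)
  as.integer(ks[hit[1]])
}

#' Segment a session into inter-switch blocks
#'
#' Partitions the trial table at `rule_switch` boundaries (a switch index is
#' the last trial of the old block). Each block is labeled with its relevant
#' modality and the shift type that ended it (`"open"` for the terminal
#' partial block).
#'
#' @param log a `session_log`, or a trial tibble (then supply `switches`).
#' @param switches optional tibble with `trial_index` and `shift_type`
#'   (overrides the log's own switch table).
#' @return tibble with one row per block: `block`, `start`, `end`,
#'   `n_trials`, `relevant_modality`, `ended_by`.
#' @export
segment_blocks <- function(log, switches = NULL) {
  if (inherits(log, "session_log")) {
    trials <- log$trials
    if (is.null(switches)) switches <- log$shifts
  } else {
    trials <- log
    if (is.null(switches)) {
      switches <- tibble(trial_index = integer(0), shift_type = character(0))
    }
  }
  n <- nrow(trials)
  s <- switches$trial_index
  if (any(s < 1 | s > n)) {
    abort("rule_switch at a nonexistent trial index")
  }
  starts <- c(1L, s + 1L)
  ends <- c(s, n)
  keep <- starts <= ends  # a switch on the final trial leaves no open block
  starts <- starts[keep]; ends <- ends[keep]
  tibble(
    block = seq_along(starts),
    start = as.integer(starts), end = as.integer(ends),
    n_trials = as.integer(ends - starts + 1L),
    relevant_modality = trials$relevant_modality[starts],
    ended_by = c(switches$shift_type, "open")[keep]
  )
}

#' Label trials around each rule switch
#'
#' For every switch, takes the `pre` trials before it (offsets `-pre..-1`)
#' and the `post` trials after it (offset 0 is the first trial under the new
#' rule) and labels them with their offset, timing (`"pre"`/`"post"`),
#' congruency and modality rule. Response trials only.
#'
#' @param log a `session_log` or trial tibble.
#' @param switches switch trial indices (tibble as in [segment_blocks()]).
#' @param pre,post window sizes in trials.
#' @param session identifier carried into the output.
#' @return tibble of labeled periswitch trials.
#' @export
periswitch_trials <- function(log, switches = NULL, pre = 10L, post = 10L,
                              session = 1L) {
  if (inherits(log, "session_log")) {
    trials <- log$trials
    if (is.null(switches)) switches <- log$shifts
  } else {
    trials <- log
  }
  if (is.null(switches) || nrow(switches) == 0) {
    abort("no rule switches to align to")
  }
  n <- nrow(trials)
  out <- vector("list", nrow(switches))
  for (j in seq_len(nrow(switches))) {
    s <- switches$trial_index[j]
    idx <- (s - pre + 1L):(s + post)
    idx <- idx[idx >= 1L & idx <= n]
    sl <- trials[idx, ]
    # offset -pre..-1 before the switch; 0 is the first trial under the
    # new rule, running to post-1
    sl$session <- session
    sl$switch_id <- j
    sl$offset <- as.integer(idx - s - 1L)
    sl$timing <- ifelse(idx <= s, "pre", "post")
    out[[j]] <- sl
  }
  res <- dplyr::bind_rows(out)
  res <- dplyr::filter(res, .data$first_response != "none")
  res$congruency <- ifelse(res$congruent, "congruent", "incongruent")
  res$modality <- res$relevant_modality
  res
}

#' Switch-aligned accuracy summary
#'
#' Aligns trials at every rule switch (offset 0 = first trial under the new
#' rule), averages accuracy per offset — overall and split by congruency —
#' and fills the modality-rule x congruency x timing cell table used by the
#' factorial analysis.
#'
#' @param logs a `session_log` or list of them.
#' @param pre,post window sizes in trials (defaults 10 and 10).
#' @return a `switch_aligned_summary`: list with `by_offset`,
#'   `by_offset_congruency`, `cells`, and the labeled `trials`.
#' @export
switch_aligned <- function(logs, pre = 10L, post = 10L) {
  if (inherits(logs, "session_log")) logs <- list(logs)
  lab <- purrr::imap(logs, function(l, i) {
    if (nrow(l$shifts) == 0) return(NULL)
    periswitch_trials(l, pre = pre, post = post, session = i)
  })
  lab <- dplyr::bind_rows(lab)
  if (nrow(lab) == 0) abort("no rule switches to align to")
  by_offset <- lab |>
    dplyr::group_by(.data$offset) |>
    dplyr::summarise(mean_accuracy = mean(.data$correct),
                     sd_accuracy = stats::sd(.data$correct),
                     n = dplyr::n(), .groups = "drop")
  by_offset_congruency <- lab |>
    dplyr::group_by(.data$offset, .data$congruency) |>
    dplyr::summarise(mean_accuracy = mean(.data$correct),
                     sd_accuracy = stats::sd(.data$correct),
                     n = dplyr::n(), .groups = "drop")
  cells <- lab |>
    dplyr::group_by(.data$modality, .data$congruency, .data$timing) |>
    dplyr::summarise(mean_accuracy = mean(.data$correct),
                     sd_accuracy = stats::sd(.data$correct),
                     n = dplyr::n(), .groups = "drop")
  structure(list(by_offset = by_offset,
                 by_offset_congruency = by_offset_congruency,
                 cells = cells, trials = lab),
            class = "switch_aligned_summary")
}

#' @export
print.switch_aligned_summary <- function(x, ...) {
  cat("<switch_aligned_summary>", nrow(x$trials), "periswitch trials,",
      length(unique(paste(x$trials$session, x$trials$switch_id))),
      "switches\n")
  print(x$cells)
  invisible(x)
}

#' Tidy a switch-aligned summary (the factorial cell table)
#'
#' @param x a `switch_aligned_summary`.
#' @param ... unused.
#' @export
tidy.switch_aligned_summary <- function(x, ...) x$cells

#' Factorial ANOVA on periswitch accuracy
#'
#' Fixed-effects factorial analysis of per-trial correctness over modality
#' rule, congruency and trial timing (pre/post switch), with the three
#' pairwise interactions. Periswitch cell counts are inherently unbalanced,
#' so marginal (type III) sums of squares with sum-to-zero contrasts are the
#' default; sequential (type I) is available.
#'
#' @param trials labeled periswitch trials (from [periswitch_trials()] or
#'   `switch_aligned()$trials`): needs `correct`, `modality`, `congruency`,
#'   `timing`.
#' @param type `"III"` (marginal) or `"I"` (sequential).
#' @return an `anova_table` tibble: `effect`, `sumsq`, `df`, `statistic`,
#'   `p.value`, plus a residuals row.
#' @export
periswitch_anova <- function(trials, type = c("III", "I")) {
  type <- match.arg(type)
  for (f in c("modality", "congruency", "timing")) {
    lev <- unique(trials[[f]])
    if (length(lev) < 2) {
      abort(paste0("factor '", f, "' has a single level ('", lev,
                   "'); both levels are required"))
    }
  }
  dat <- data.frame(
    y = as.numeric(trials$correct),
    modality = factor(trials$modality),
    congruency = factor(trials$congruency),
    timing = factor(trials$timing)
  )
  if (type == "III") {
    m <- lm(y ~ (modality + congruency + timing)^2, data = dat,
            contrasts = list(modality = "contr.sum",
                             congruency = "contr.sum",
                             timing = "contr.sum"))
    a <- car::Anova(m, type = 3)
    a <- a[!rownames(a) %in% "(Intercept)", ]
  } else {
    m <- lm(y ~ (modality + congruency + timing)^2, data = dat)
    a <- stats::anova(m)
  }
  tab <- tibble(
    effect = sub("Residuals", "residuals", rownames(a)),
    sumsq = a[["Sum Sq"]],
    df = a[["Df"]],
    statistic = a[["F value"]],
    p.value = a[["Pr(>F)"]]
  )
  structure(tab, class = c("anova_table", class(tab)))
}

#' Bonferroni-corrected pairwise group comparisons
#'
#' Pairwise t-tests of per-trial correctness across the factorial cells
#' (modality x congruency x timing), Bonferroni-corrected over group pairs.
#'
#' @param trials labeled periswitch trials (see [periswitch_anova()]).
#' @return tibble `(group1, group2, p.value)` with corrected p values.
#' @export
periswitch_posthoc <- function(trials) {
  g <- interaction(trials$modality, trials$congruency, trials$timing,
                   sep = "/", drop = TRUE)
  pt <- stats::pairwise.t.test(as.numeric(trials$correct), g,
                               p.adjust.method = "bonferroni")
  m <- pt$p.value
  out <- list()
  for (i in seq_len(nrow(m))) {
    for (j in seq_len(ncol(m))) {
      if (!is.na(m[i, j])) {
        out[[length(out) + 1L]] <- tibble(group1 = rownames(m)[i],
                                          group2 = colnames(m)[j],
                                          p.value = m[i, j])
      }
    }
  }
  dplyr::bind_rows(out)
}

#' Peri-event lick histogram
#'
#' Bins lick events relative to an alignment event (one per trial), per
#' side, normalized to a rate in Hz: `count / (n_alignments * bin_s)`.
#'
#' @param events event tibble (needs `t_ms`, `kind`, `side`).
#' @param align_to event kind to align to (default the response-window
#'   opening).
#' @param bin_ms bin width.
#' @param window `[lo, hi]` ms around the alignment event.
#' @return tibble `(bin_lo_ms, bin_mid_ms, side, count, rate_hz)`.
#' @export
lick_psth <- function(events, align_to = "response_window_on", bin_ms = 100L,
                      window = c(-2500L, 1500L)) {
  stopifnot(bin_ms >= 1)
  anchors <- events$t_ms[events$kind == align_to]
  if (!length(anchors)) abort(paste0("no '", align_to, "' events to align to"))
  licks <- events[events$kind %in% c("lick_left", "lick_right"), ]
  breaks <- seq(window[1], window[2], by = bin_ms)
  if (breaks[length(breaks)] < window[2]) breaks <- c(breaks, window[2])
  grid <- tidyr::expand_grid(bin_lo_ms = breaks[-length(breaks)],
                             side = SIDES)
  counts <- grid
  counts$count <- 0L
  if (nrow(licks)) {
    # each lick is assigned to the nearest preceding anchor of its trial
    anchor_by_trial <- stats::setNames(
      events$t_ms[events$kind == align_to],
      events$trial_index[events$kind == align_to])
    rel <- licks$t_ms - anchor_by_trial[as.character(licks$trial_index)]
    keep <- !is.na(rel) & rel >= window[1] & rel < window[2]
    if (any(keep)) {
      bin <- breaks[findInterval(rel[keep], breaks)]
      tab <- tibble(bin_lo_ms = bin, side = licks$side[keep]) |>
        dplyr::count(.data$bin_lo_ms, .data$side, name = "count")
      counts <- dplyr::rows_update(counts, tab,
                                   by = c("bin_lo_ms", "side"))
    }
  }
  counts$bin_mid_ms <- counts$bin_lo_ms + bin_ms / 2
  counts$rate_hz <- counts$count / (length(anchors) * bin_ms / 1000)
  counts[c("bin_lo_ms", "bin_mid_ms", "side", "count", "rate_hz")]
}

#' Per-session summaries
#'
#' Exact counts from one or more session logs: trials, blocks, switches,
#' response rate, accuracy, consumed volume and termination reason.
#'
#' @param logs a `session_log` or list of them.
#' @return tibble, one row per session.
#' @export
session_summary <- function(logs) {
  if (inherits(logs, "session_log")) logs <- list(logs)
  if (!length(logs)) {
    return(tibble(session = integer(0), stage_id = character(0),
                  n_trials = integer(0), n_blocks = integer(0),
                  n_switches = integer(0), response_rate = numeric(0),
                  accuracy = numeric(0), total_volume_ul = numeric(0),
                  terminated_by = character(0)))
  }
  dplyr::bind_rows(purrr::imap(logs, function(l, i) {
    dplyr::bind_cols(tibble(session = i), glance(l))
  }))
}
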
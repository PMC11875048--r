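EVENT_KEYS <- c("t_ms", "trial_index", "kind", "side", "exemplar",
                "volume_ul", "shift_type", "rule_before", "rule_after")

# One JSON object per event line, keys always in EVENT_KEYS order, absent
# fields omitted, sides printed as "L"/"R"; built vectorized so identical
# runs produce identical bytes.
events_to_jsonl <- function(events) {
  piece <- function(key, val, quote) {
    out <- character(length(val))
    ok <- !is.na(val)
    v <- if (quote) paste0("\"", val[ok], "\"") else format(val[ok],
                                                            scientific = FALSE,
                                                            trim = TRUE)
    out[ok] <- paste0(",\"", key, "\":", v)
    out
  }
  side <- ifelse(is.na(events$side), NA_character_,
                 unname(side_to_code(events$side)))
  paste0(
    "{\"t_ms\":", events$t_ms,
    ",\"trial_index\":", events$trial_index,
    ",\"kind\":\"", events$kind, "\"",
    piece("side", side, TRUE),
    piece("exemplar", events$exemplar, TRUE),
    piece("volume_ul", events$volume_ul, FALSE),
    piece("shift_type", events$shift_type, TRUE),
    piece("rule_before", events$rule_before, TRUE),
    piece("rule_after", events$rule_after, TRUE),
    "}"
  )
}

jsonl_to_events <- function(lines) {
  rows <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    rows[[i]] <- tryCatch(
      jsonlite::fromJSON(lines[i]),
      error = function(e) abort(paste0("events line ", i, ": malformed JSON"))
    )
  }
  get_chr <- function(key) {
    vapply(rows, function(r) {
      if (is.null(r[[key]])) NA_character_ else as.character(r[[key]])
    }, NA_character_)
  }
  get_int <- function(key) {
    vapply(rows, function(r) {
      if (is.null(r[[key]])) NA_integer_ else as.integer(r[[key]])
    }, NA_integer_)
  }
  get_dbl <- function(key) {
    vapply(rows, function(r) {
      if (is.null(r[[key]])) NA_real_ else as.numeric(r[[key]])
    }, NA_real_)
  }
  side <- get_chr("side")
  tibble(
    t_ms = get_int("t_ms"),
    trial_index = get_int("trial_index"),
    kind = get_chr("kind"),
    side = ifelse(is.na(side), NA_character_, unname(code_to_side(side))),
    exemplar = get_chr("exemplar"),
    volume_ul = get_dbl("volume_ul"),
    shift_type = get_chr("shift_type"),
    rule_before = get_chr("rule_before"),
    rule_after = get_chr("rule_after")
  )
}

trials_for_csv <- function(trials) {
  tr <- trials
  tr$rewarded_side <- unname(side_to_code(tr$rewarded_side))
  tr$first_response <- unname(side_to_code(tr$first_response))
  tr$relevant_modality <- tr$relevant_modality
  tr
}

trials_from_csv <- function(tr) {
  tr$rewarded_side <- unname(code_to_side(tr$rewarded_side))
  tr$first_response <- unname(code_to_side(tr$first_response))
  for (f in c("trial_index", "block_index", "t_start_ms", "t_end_ms",
              "iti_ms")) {
    tr[[f]] <- as.integer(tr[[f]])
  }
  for (f in c("congruent", "correct", "rewarded")) {
    tr[[f]] <- as.logical(tr[[f]])
  }
  tr$reward_volume_ul <- as.numeric(tr$reward_volume_ul)
  tr
}

#' Write a session log (or cohort) as a log bundle
#'
#' A bundle directory holds `events.jsonl` (one event per line, fixed key
#' order), `trials.csv` (one trial per row, sides printed `L`/`R`),
#' `config.yml`, and `manifest.yml` carrying the package version, the seed,
#' the termination record and an MD5 digest of the serialized config. Field
#' ordering is stable, so identical runs produce byte-identical bundles.
#' A cohort is written as one sub-bundle per agent session.
#'
#' @param log a `session_log` or a `cohort`.
#' @param directory target directory (created if needed).
#' @return the bundle manifest (invisibly a `log_bundle` list).
#' @export
write_bundle <- function(log, directory) {
  if (inherits(log, "cohort")) return(write_cohort_bundle(log, directory))
  stopifnot(inherits(log, "session_log"))
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory)) abort(paste0("cannot create '", directory, "'"))
  cfg_path <- file.path(directory, "config.yml")
  write_config(log$config, cfg_path)
  writeLines(events_to_jsonl(log$events), file.path(directory, "events.jsonl"))
  readr::write_csv(trials_for_csv(log$trials),
                   file.path(directory, "trials.csv"), progress = FALSE)
  manifest <- list(
    format = "setshiftr-bundle-1",
    package_version = as.character(utils::packageVersion("setshiftr")),
    stage_id = log$config$stage_id,
    seed = log$config$seed,
    config_digest = unname(tools::md5sum(cfg_path)),
    n_trials = nrow(log$trials),
    n_switches = nrow(log$shifts),
    total_volume_ul = log$total_volume_ul,
    terminated_by = log$terminated_by
  )
  yaml::write_yaml(manifest, file.path(directory, "manifest.yml"))
  invisible(structure(c(manifest, list(path = directory)),
                      class = "log_bundle"))
}

write_cohort_bundle <- function(cohort, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(cohort)) {
    adir <- file.path(directory, sprintf("agent-%02d", i))
    dir.create(adir, recursive = TRUE, showWarnings = FALSE)
    yaml::write_yaml(unclass(cohort[[i]]$params),
                     file.path(adir, "agent.yml"), precision = 15)
    for (s in seq_along(cohort[[i]]$logs)) {
      write_bundle(cohort[[i]]$logs[[s]],
                   file.path(adir, sprintf("session-%02d", s)))
    }
  }
  manifest <- list(format = "setshiftr-cohort-1", n_agents = length(cohort),
                   sessions_per_agent = length(cohort[[1]]$logs))
  yaml::write_yaml(manifest, file.path(directory, "manifest.yml"))
  invisible(structure(c(manifest, list(path = directory)),
                      class = "log_bundle"))
}

check_trial_invariants <- function(tr) {
  for (i in seq_len(nrow(tr))) {
    r <- tr[i, ]
    if (r$first_response != "none" &&
        !identical(r$correct, r$first_response == r$rewarded_side)) {
      abort(paste0("trials.csv row ", i,
                   ": correct does not match first_response vs rewarded_side"))
    }
    if (r$rewarded && r$reward_volume_ul <= 0) {
      abort(paste0("trials.csv row ", i,
                   ": rewarded trial with zero reward volume"))
    }
    if (!r$rewarded && r$reward_volume_ul != 0) {
      abort(paste0("trials.csv row ", i,
                   ": unrewarded trial with nonzero reward volume"))
    }
  }
  invisible(tr)
}

#' Read a log bundle back into a session log
#'
#' Reconstructs the `session_log` from a bundle directory, verifying the
#' manifest's config digest, per-row trial invariants (corrupt rows are
#' rejected with their row number) and per-trial event-time monotonicity.
#'
#' @param directory bundle directory.
#' @return a `session_log`, or a `cohort` for cohort bundles.
#' @export
read_bundle <- function(directory) {
  man_path <- file.path(directory, "manifest.yml")
  if (!file.exists(man_path)) abort(paste0("missing manifest: ", man_path))
  manifest <- yaml::read_yaml(man_path)
  if (identical(manifest$format, "setshiftr-cohort-1")) {
    return(read_cohort_bundle(directory, manifest))
  }
  for (f in c("config.yml", "events.jsonl", "trials.csv")) {
    if (!file.exists(file.path(directory, f))) {
      abort(paste0("incomplete bundle: missing ", f))
    }
  }
  cfg_path <- file.path(directory, "config.yml")
  digest <- unname(tools::md5sum(cfg_path))
  if (!identical(digest, manifest$config_digest)) {
    abort("config.yml does not match the manifest digest")
  }
  config <- read_config(cfg_path)
  lines <- readLines(file.path(directory, "events.jsonl"))
  events <- jsonl_to_events(lines)
  tr <- readr::read_csv(file.path(directory, "trials.csv"),
                        show_col_types = FALSE, progress = FALSE)
  tr <- trials_from_csv(tr)
  check_trial_invariants(tr)
  bad <- which(
    vapply(split(events$t_ms, events$trial_index),
           function(t) any(diff(t) < 0), TRUE))
  if (length(bad)) {
    abort(paste0("events for trial ", names(bad)[1],
                 " are not nondecreasing in time"))
  }
  sw <- events[events$kind == "rule_switch", ]
  shifts <- tibble(trial_index = sw$trial_index, shift_type = sw$shift_type,
                   rule_before = sw$rule_before, rule_after = sw$rule_after)
  structure(
    list(config = config, trials = tr, events = events, shifts = shifts,
         total_volume_ul = sum(tr$reward_volume_ul),
         terminated_by = manifest$terminated_by,
         final_rule = NULL, final_agent = NULL),
    class = "session_log"
  )
}

read_cohort_bundle <- function(directory, manifest) {
  out <- vector("list", manifest$n_agents)
  for (i in seq_len(manifest$n_agents)) {
    adir <- file.path(directory, sprintf("agent-%02d", i))
    params <- do.call(agent_params, yaml::read_yaml(file.path(adir, "agent.yml")))
    sdirs <- sort(list.dirs(adir, recursive = FALSE))
    out[[i]] <- list(params = params, logs = lapply(sdirs, read_bundle))
  }
  structure(out, class = "cohort")
}

#' Read agent parameters from a YAML file
#'
#' Same structured-text format as the session configuration; unknown keys
#' are an error.
#'
#' @param path YAML file of [agent_params()] fields.
#' @return an `agent_params`.
#' @export
read_agent_params <- function(path) {
  x <- yaml::read_yaml(path)
  unknown <- setdiff(names(x), names(agent_params()))
  if (length(unknown)) {
    abort(paste0("unknown agent parameter(s): ",
                 paste(unknown, collapse = ", ")))
  }
  do.call(agent_params, x)
}
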
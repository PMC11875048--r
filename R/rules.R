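#' Default stimulus-exemplar pools
#'
#' Two to four identified cues per modality. The default whisker pool holds
#' four vibration patterns (a 210 Hz tone-like vibration, a Poisson
#' quasi-square-wave pulse train, and two spares) and the odor pool four
#' odorants diluted 1:100 in mineral oil.
#'
#' @return a tibble with columns `modality`, `exemplar_id`, `descriptor`.
#' @export
exemplar_pools <- function() {
  tibble(
    modality = c(rep("whisker", 4), rep("odor", 4)),
    exemplar_id = c("W1", "W2", "W3", "W4", "O1", "O2", "O3", "O4"),
    descriptor = c("210 Hz vibration", "Poisson pulse train",
                   "155 Hz vibration", "85 Hz vibration",
                   "eugenol 1:100", "benzaldehyde 1:100",
                   "isoamyl acetate 1:100", "limonene 1:100")
  )
}

validate_pools <- function(pools) {
  counts <- table(pools$modality)
  for (m in c("whisker", "odor")) {
    n <- if (m %in% names(counts)) counts[[m]] else 0L
    if (n < 2 || n > 4) {
      abort(paste0(m, " pool must contain between 2 and 4 exemplars"))
    }
  }
  if (anyDuplicated(pools[c("modality", "exemplar_id")])) {
    abort("exemplar_id must be unique within a modality pool")
  }
  invisible(pools)
}

validate_map <- function(map, what) {
  if (length(map) != 2 || !setequal(unname(map), SIDES)) {
    abort(paste0(what, " must map exactly one exemplar to left and one to right"))
  }
  invisible(map)
}

#' Task rule state
#'
#' The currently relevant modality plus the latent exemplar-to-side mappings
#' for both modalities. Both maps are always defined, including for the
#' distractor modality, so that congruency can be labeled on every compound
#' trial. Each active map is a named character vector assigning one exemplar
#' to `"left"` and one to `"right"`.
#'
#' @param relevant_modality `"whisker"` or `"odor"`.
#' @param whisker_map,odor_map named character vectors, e.g.
#'   `c(W1 = "left", W2 = "right")`.
#' @param block_index current block number (0-based; a block is the run of
#'   trials between consecutive rule switches).
#' @param trials_in_block trials already run in the current block.
#' @param used_exemplars exemplars already consumed by earlier blocks
#'   (intradimensional shifts may only introduce never-used exemplars);
#'   defaults to the active ones.
#' @return a `rule_state` object.
#' @export
rule_state <- function(relevant_modality = "whisker",
                       whisker_map = c(W1 = "left", W2 = "right"),
                       odor_map = c(O1 = "left", O2 = "right"),
                       block_index = 0L, trials_in_block = 0L,
                       used_exemplars = NULL) {
  stopifnot(relevant_modality %in% c("whisker", "odor"))
  validate_map(whisker_map, "whisker_map")
  validate_map(odor_map, "odor_map")
  structure(
    list(relevant_modality = relevant_modality,
         whisker_map = whisker_map, odor_map = odor_map,
         block_index = as.integer(block_index),
         trials_in_block = as.integer(trials_in_block),
         used_exemplars = used_exemplars %||%
           c(names(whisker_map), names(odor_map))),
    class = "rule_state"
  )
}

relevant_map <- function(rule) {
  if (rule$relevant_modality == "whisker") rule$whisker_map else rule$odor_map
}

irrelevant_map <- function(rule) {
  if (rule$relevant_modality == "whisker") rule$odor_map else rule$whisker_map
}

#' Congruency of a compound stimulus
#'
#' A compound trial is congruent when the two latent maps send the presented
#' whisker and odor exemplars to the same reward side, so the correct
#' response does not depend on which modality is currently relevant.
#' Congruency is undefined (`NA`) when either stimulus is absent.
#'
#' @param rule a [rule_state()].
#' @param whisker_stim,odor_stim exemplar ids or `NA`.
#' @return logical (`NA` when only one modality is presented).
#' @export
trial_congruent <- function(rule, whisker_stim, odor_stim) {
  if (is.na(whisker_stim) || is.na(odor_stim)) return(NA)
  unname(rule$whisker_map[whisker_stim] == rule$odor_map[odor_stim])
}

encode_map <- function(map) {
  paste(names(map), side_to_code(unname(map)), sep = "=", collapse = ",")
}

encode_rule <- function(rule) {
  paste0(rule$relevant_modality, "|w:", encode_map(rule$whisker_map),
         "|o:", encode_map(rule$odor_map))
}

decode_rule <- function(txt, block_index = 0L, trials_in_block = 0L) {
  parts <- strsplit(txt, "|", fixed = TRUE)[[1]]
  parse_map <- function(s) {
    kv <- strsplit(strsplit(sub("^[wo]:", "", s), ",")[[1]], "=")
    setNames(unname(code_to_side(vapply(kv, `[`, "", 2))),
             vapply(kv, `[`, "", 1))
  }
  rule_state(parts[1], parse_map(parts[2]), parse_map(parts[3]),
             block_index, trials_in_block)
}

#' Apply a rule shift
#'
#' Transforms a rule state by one of the three cognitive-flexibility
#' manipulations: an intradimensional shift (`"IDS"`) replaces the relevant
#' modality's exemplars with previously unused ones from its pool; a reversal
#' (`"Rev"`) swaps the left/right assignments of the relevant map; an
#' extradimensional shift (`"EDS"`) toggles which modality is relevant,
#' leaving both maps unchanged. The block index is incremented and the
#' within-block trial counter reset.
#'
#' @param rule a [rule_state()].
#' @param shift_type `"IDS"`, `"Rev"` or `"EDS"`.
#' @param pools exemplar pools (see [exemplar_pools()]); only needed for IDS.
#' @return a `shift_event` list with `shift_type`, `rule_before`,
#'   `rule_after`, and `trial_index` (`NA` until logged by a session).
#' @export
apply_shift <- function(rule, shift_type, pools = exemplar_pools()) {
  after <- switch(shift_type,
    Rev = {
      r <- rule
      if (r$relevant_modality == "whisker") {
        r$whisker_map[] <- other_side(r$whisker_map)
      } else {
        r$odor_map[] <- other_side(r$odor_map)
      }
      r
    },
    EDS = {
      r <- rule
      r$relevant_modality <- other_side_modality(r$relevant_modality)
      r
    },
    IDS = {
      r <- rule
      pool <- pools$exemplar_id[pools$modality == r$relevant_modality]
      fresh <- setdiff(pool, r$used_exemplars)
      if (length(fresh) < 2) {
        abort(paste0("IDS requires at least 2 unused exemplars in the ",
                     r$relevant_modality, " pool"))
      }
      newmap <- setNames(SIDES, fresh[1:2])
      if (r$relevant_modality == "whisker") r$whisker_map <- newmap
      else r$odor_map <- newmap
      r$used_exemplars <- c(r$used_exemplars, fresh[1:2])
      r
    },
    abort(paste0("unknown shift type '", shift_type, "'"))
  )
  after$block_index <- rule$block_index + 1L
  after$trials_in_block <- 0L
  structure(
    list(trial_index = NA_integer_, shift_type = shift_type,
         rule_before = rule, rule_after = after),
    class = "shift_event"
  )
}

other_side_modality <- function(m) if (m == "whisker") "odor" else "whisker"
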
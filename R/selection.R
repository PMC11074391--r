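## Data-selection cascade: incomplete-prompt removal, double-completion
## dedup, compliance filtering, and the retention log.

retention_row <- function(stage, records) {
  data.frame(
    stage = stage,
    n_prompts = nrow(records),
    n_participants = length(unique(records$participant_id)),
    n_days = length(unique(paste(records$participant_id, records$day))),
    stringsAsFactors = FALSE
  )
}

#' Remove prompts with incomplete emotion data
#'
#' A prompt is incomplete when any of the six PA/NA emotion items is
#' unanswered; the tiredness item does not count. Incomplete prompts are
#' removed before any compliance accounting.
#'
#' @inheritParams validate_prompts
#' @return The retained (complete) prompt records.
#' @export
drop_incomplete_prompts <- function(records, design = ema_design()) {
  core <- as.matrix(records[c(design$pa_items, design$na_items)])
  records[rowSums(is.na(core)) == 0L, , drop = FALSE]
}

#' Resolve double completions of the same prompt
#'
#' When a (participant, day, slot) key occurs more than once, only the
#' first completion is retained: the earliest timestamp, or the first row
#' in file order when timestamps are missing or tied.
#'
#' @inheritParams validate_prompts
#' @return Records with one row per (participant, day, slot) key.
#' @export
dedupe_double_completion <- function(records) {
  if (nrow(records) == 0L) return(records)
  ts <- if ("timestamp" %in% names(records)) records$timestamp
        else rep(NA_character_, nrow(records))
  # stable order: key, then timestamp (NA last), then file order
  ord <- order(records$participant_id, records$day, records$slot,
               is.na(ts), ts, seq_len(nrow(records)))
  sorted <- records[ord, , drop = FALSE]
  key <- paste(sorted$participant_id, sorted$day, sorted$slot)
  kept <- sorted[!duplicated(key), , drop = FALSE]
  # restore original file order among kept rows
  kept[order(as.integer(rownames(kept))), , drop = FALSE]
}

#' Apply the compliance filters
#'
#' Applies, in order: (1) drop participants with fewer than
#' `min_total_prompts` answered prompts; (2) drop person-days with fewer
#' than `min_prompts_per_day` prompts; (3) drop participants left with
#' fewer than `min_valid_days` days. The ordering matters: the total-prompt
#' count at stage 1 includes prompts on days that stage 2 later removes.
#'
#' @inheritParams validate_prompts
#' @param records Complete, deduplicated prompt records.
#' @return A list with elements `records` (the retained prompts) and
#'   `retention` (a data frame logging prompts, participants and
#'   person-days remaining after each stage).
#' @export
apply_compliance_filters <- function(records, design = ema_design()) {
  log <- retention_row("input", records)

  # stage 1: minimum total answered prompts per participant
  n_per <- table(records$participant_id)
  keep <- names(n_per)[n_per >= design$min_total_prompts]
  records <- records[records$participant_id %in% keep, , drop = FALSE]
  log <- rbind(log, retention_row("min_total_prompts", records))

  # stage 2: minimum prompts per person-day
  day_key <- paste(records$participant_id, records$day)
  n_day <- table(day_key)
  keep_days <- names(n_day)[n_day >= design$min_prompts_per_day]
  records <- records[day_key %in% keep_days, , drop = FALSE]
  log <- rbind(log, retention_row("min_prompts_per_day", records))

  # stage 3: minimum number of valid days per participant
  days_per <- tapply(records$day, records$participant_id,
                     function(d) length(unique(d)))
  keep <- names(days_per)[days_per >= design$min_valid_days]
  records <- records[records$participant_id %in% keep, , drop = FALSE]
  log <- rbind(log, retention_row("min_valid_days", records))

  list(records = records, retention = log)
}

#' Join filtered EMA records with participant outcomes
#'
#' Inner join on `participant_id`. Participants without symptom data
#' (absent from `outcomes`, or with both subscale totals missing) are
#' excluded; participants missing only one subscale are retained and
#' handled by per-model listwise deletion.
#'
#' @param records Filtered prompt records.
#' @param outcomes Participant outcomes from [score_participants()].
#' @return A list with `records` (prompts of retained participants),
#'   `outcomes` (matching outcome rows) and `excluded` (dropped ids).
#' @export
join_outcomes <- function(records, outcomes) {
  if (anyDuplicated(outcomes$participant_id))
    stop("duplicate participant_id in outcomes")
  has_any <- !(is.na(outcomes$dep_total) & is.na(outcomes$anx_total))
  usable <- outcomes$participant_id[has_any]
  ids <- unique(records$participant_id)
  keep <- intersect(ids, usable)
  list(
    records = records[records$participant_id %in% keep, , drop = FALSE],
    outcomes = outcomes[match(keep, outcomes$participant_id), , drop = FALSE],
    excluded = setdiff(ids, keep)
  )
}

#' Run the full data-selection cascade
#'
#' Convenience wrapper: validation, incomplete-prompt removal, double
#' completion dedup, and the three compliance filters, with a retention
#' log covering every stage.
#'
#' @inheritParams validate_prompts
#' @return A list with `records` and the full `retention` log.
#' @export
preprocess_ema <- function(records, design = ema_design()) {
  validate_prompts(records, design, allow_duplicates = TRUE)
  log <- retention_row("raw", records)
  records <- drop_incomplete_prompts(records, design)
  log <- rbind(log, retention_row("complete_prompts", records))
  records <- dedupe_double_completion(records)
  log <- rbind(log, retention_row("deduplicated", records))
  validate_prompts(records, design, allow_duplicates = FALSE)
  out <- apply_compliance_filters(records, design)
  log <- rbind(log, out$retention[-1L, , drop = FALSE])
  list(records = out$records, retention = log)
}
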
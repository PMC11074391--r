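#' Emotion items used at every EMA prompt
#'
#' Seven momentary emotion items, each rated on a 7-point scale from
#' 0 ("not at all") to 6 ("very strongly"). The first two items measure
#' positive affect (PA), the next four negative affect (NA); the
#' tiredness/listlessness item is carried through I/O but used by no
#' emotion-dynamics index.
#'
#' @format Character vector of length 7.
#' @export
ema_items <- c(
  "joy_excitement",
  "satisfaction_relaxation",
  "worry_anxiety",
  "sadness_disappointment",
  "irritation_anger",
  "tension_stress",
  "tiredness_listlessness"
)

#' Study design for an EMA protocol
#'
#' Describes the sampling scheme (days x prompts per day), the compliance
#' thresholds applied during data selection, and which items form the PA
#' and NA composites. Defaults follow a 7-day, 5-prompt protocol with
#' the "at least 10 of 35 prompts, at least 3 prompts on at least 3 days"
#' inclusion rule.
#'
#' @param n_days Number of study days.
#' @param prompts_per_day Scheduled prompts per day.
#' @param min_total_prompts Minimum answered prompts per participant
#'   (30 percent of the 35 scheduled prompts by default).
#' @param min_prompts_per_day Minimum answered prompts for a person-day to
#'   count as a valid day.
#' @param min_valid_days Minimum number of valid days per participant.
#' @param pa_items,na_items Item names forming the positive / negative
#'   affect composites; must be disjoint subsets of `items`.
#' @param items All emotion item names expected in a prompt record.
#'
#' @return An object of class `"ema_design"` (a named list).
#' @examples
#' d <- ema_design()
#' d$min_total_prompts
#' @export
ema_design <- function(n_days = 7L,
                       prompts_per_day = 5L,
                       min_total_prompts = 10L,
                       min_prompts_per_day = 3L,
                       min_valid_days = 3L,
                       pa_items = ema_items[1:2],
                       na_items = ema_items[3:6],
                       items = ema_items) {
  n_days <- as.integer(n_days)
  prompts_per_day <- as.integer(prompts_per_day)
  stopifnot(n_days >= 1L, prompts_per_day >= 1L)
  if (min_total_prompts > n_days * prompts_per_day)
    stop("min_total_prompts exceeds the number of scheduled prompts")
  if (length(intersect(pa_items, na_items)) > 0L)
    stop("pa_items and na_items must be disjoint")
  if (!all(c(pa_items, na_items) %in% items))
    stop("pa_items and na_items must be a subset of items")
  structure(
    list(
      n_days = n_days,
      prompts_per_day = prompts_per_day,
      min_total_prompts = as.integer(min_total_prompts),
      min_prompts_per_day = as.integer(min_prompts_per_day),
      min_valid_days = as.integer(min_valid_days),
      pa_items = pa_items,
      na_items = na_items,
      items = items
    ),
    class = "ema_design"
  )
}

#' @export
print.ema_design <- function(x, ...) {
  cat("EMA study design:", x$n_days, "days x", x$prompts_per_day,
      "prompts/day\n")
  cat("Compliance: >=", x$min_total_prompts, "prompts total; >=",
      x$min_prompts_per_day, "prompts/day on >=", x$min_valid_days,
      "days\n")
  cat("PA items:", paste(x$pa_items, collapse = ", "), "\n")
  cat("NA items:", paste(x$na_items, collapse = ", "), "\n")
  invisible(x)
}

#' Validate long-format EMA prompt records
#'
#' Checks a long-format prompt table against a study design: required
#' columns, integer ratings within 0..6, day and slot indices within the
#' design bounds, and (optionally) uniqueness of the
#' (participant, day, slot) key. Violations are reported with row numbers
#' rather than silently dropped.
#'
#' @param records Data frame with columns `participant_id`, `day`, `slot`,
#'   an optional `timestamp`, and one column per design item (integer
#'   ratings 0--6; `NA` = item not answered).
#' @param design An [ema_design()].
#' @param allow_duplicates If `TRUE` (the default for raw data), duplicate
#'   (participant, day, slot) keys are tolerated; they are resolved later
#'   by [dedupe_double_completion()].
#'
#' @return `records`, invisibly, if valid; otherwise an error listing the
#'   offending rows.
#' @export
validate_prompts <- function(records, design = ema_design(),
                             allow_duplicates = TRUE) {
  required <- c("participant_id", "day", "slot", design$items)
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0L)
    stop("missing required columns: ", paste(missing_cols, collapse = ", "))

  bad <- function(rows, what) {
    if (any(rows))
      stop(what, " in rows: ",
           paste(utils::head(which(rows), 20L), collapse = ", "),
           if (sum(rows) > 20L) " ..." else "")
  }
  for (item in design$items) {
    v <- records[[item]]
    bad(!is.na(v) & (v < 0 | v > 6 | v != round(v)),
        paste0("rating out of range 0..6 for '", item, "'"))
  }
  bad(is.na(records$day) | records$day < 1 | records$day > design$n_days,
      "day index outside design bounds")
  bad(is.na(records$slot) | records$slot < 1 |
        records$slot > design$prompts_per_day,
      "slot index outside design bounds")
  if (!allow_duplicates) {
    key <- paste(records$participant_id, records$day, records$slot)
    bad(duplicated(key), "duplicate (participant, day, slot) key")
  }
  invisible(records)
}

#' Read long-format EMA prompt data
#'
#' Reads a long CSV with one row per answered prompt: columns
#' `participant_id`, `day`, `slot`, an optional ISO-8601 `timestamp`, and
#' one integer column (0--6, empty = missing) per emotion item. Every row
#' is validated; range violations raise an error naming the rows.
#' Duplicate keys are allowed at ingest (double completions are resolved
#' downstream).
#'
#' @inheritParams validate_prompts
#' @param path Path to the CSV file.
#' @return A validated data frame of prompt records.
#' @seealso [write_ema_long()], [validate_prompts()]
#' @export
read_ema_long <- function(path, design = ema_design(),
                          allow_duplicates = TRUE) {
  records <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  if (!"timestamp" %in% names(records)) records$timestamp <- NA_character_
  records$participant_id <- as.character(records$participant_id)
  for (item in design$items) {
    if (item %in% names(records)) records[[item]] <- as.integer(records[[item]])
  }
  validate_prompts(records, design, allow_duplicates = allow_duplicates)
  records
}

#' Write long-format EMA prompt data
#'
#' Inverse of [read_ema_long()]: writing then reading reproduces the
#' records exactly (ratings are integers, so the round trip is bit-exact).
#'
#' @param records Prompt records as returned by [read_ema_long()] or
#'   [simulate_cohort()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ema_long <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read the participant table
#'
#' Columns: `participant_id`, `age`, `gender` (`"f"`/`"m"`), and either
#' item-level subscale responses `dep_1..dep_8`, `anx_1..anx_6` (each
#' 0--4) or precomputed `dep_total`, `anx_total`.
#'
#' @param path Path to the CSV file.
#' @return A data frame, one row per participant.
#' @export
read_participants <- function(path) {
  meta <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  needed <- c("participant_id", "age", "gender")
  missing_cols <- setdiff(needed, names(meta))
  if (length(missing_cols) > 0L)
    stop("missing required columns: ", paste(missing_cols, collapse = ", "))
  meta$participant_id <- as.character(meta$participant_id)
  if (anyDuplicated(meta$participant_id))
    stop("duplicate participant_id in participant table")
  if (!all(meta$gender %in% c("f", "m", NA)))
    stop("gender must be coded 'f' or 'm'")
  meta
}

#' Prompt-level positive and negative affect means
#'
#' Appends `pa_mean` (mean of the 2 PA items) and `na_mean` (mean of the
#' 4 NA items) to each prompt record. The tiredness item plays no role.
#' All six PA/NA items must be present: incomplete prompts should have
#' been removed with [drop_incomplete_prompts()] first.
#'
#' @inheritParams validate_prompts
#' @return `records` with numeric columns `pa_mean` and `na_mean` added.
#' @examples
#' r <- data.frame(participant_id = "p1", day = 1, slot = 1,
#'                 joy_excitement = 4, satisfaction_relaxation = 2,
#'                 worry_anxiety = 1, sadness_disappointment = 0,
#'                 irritation_anger = 0, tension_stress = 3,
#'                 tiredness_listlessness = 5)
#' prompt_affect_means(r)[, c("pa_mean", "na_mean")]  # 3.0, 1.0
#' @export
prompt_affect_means <- function(records, design = ema_design()) {
  pa <- as.matrix(records[design$pa_items])
  na_ <- as.matrix(records[design$na_items])
  incomplete <- rowSums(is.na(pa)) > 0L | rowSums(is.na(na_)) > 0L
  if (any(incomplete))
    stop("incomplete prompts (missing PA/NA items) in rows: ",
         paste(utils::head(which(incomplete), 20L), collapse = ", "),
         "; apply drop_incomplete_prompts() first")
  records$pa_mean <- rowMeans(pa)
  records$na_mean <- rowMeans(na_)
  records
}
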
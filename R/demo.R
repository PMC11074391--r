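#' Deterministic 20-participant demonstration cohort
#'
#' A small, fully deterministic synthetic cohort exercising every branch
#' of the data-selection cascade: participants with full and partial
#' compliance, one below the minimum-prompt threshold, one whose days
#' collapse below the valid-day threshold after the day filter, one who
#' passes the total-prompt filter only because low-compliance days still
#' count at that stage, a double completion, incomplete prompts, one
#' participant without metadata, and one with a missing depression
#' subscale. Ratings follow a fixed arithmetic pattern (no RNG), so every
#' downstream number is reproducible by hand.
#'
#' @return A list with `prompts` and `participants` data frames, matching
#'   the files under `inst/extdata/`.
#' @examples
#' demo <- demo_cohort()
#' nrow(demo$prompts)  # 494 raw prompt rows
#' @export
demo_cohort <- function() {
  items <- ema_items
  mk <- function(i, day, slot, drop_item = NULL, hour_offset = 0L) {
    rec <- data.frame(
      participant_id = sprintf("P%02d", i), day = day, slot = slot,
      timestamp = sprintf("2021-05-%02dT%02d:00:00", 9L + day,
                          8L + 2L * slot + hour_offset),
      stringsAsFactors = FALSE
    )
    for (k in seq_along(items)) {
      v <- (i * 3L + day * 5L + slot * (2L + k) + k * 11L) %% 7L
      rec[[items[k]]] <- if (!is.null(drop_item) && items[k] == drop_item)
        NA_integer_ else v
    }
    rec
  }
  days_grid <- function(i, counts, ...) {
    do.call(rbind, lapply(seq_along(counts), function(d) {
      if (counts[d] == 0L) return(NULL)
      do.call(rbind, lapply(seq_len(counts[d]), function(s) mk(i, d, s, ...)))
    }))
  }

  rows <- list()
  for (i in 1:8) rows[[i]] <- days_grid(i, rep(5L, 7L))        # full weeks
  rows[[9]] <- rbind(days_grid(9L, rep(4L, 5L)),               # 20 complete
                     mk(9L, 6L, 1L, drop_item = "worry_anxiety"),
                     mk(9L, 6L, 2L, drop_item = "worry_anxiety"))
  rows[[10]] <- days_grid(10L, rep(3L, 7L))                    # 21
  rows[[11]] <- days_grid(11L, c(3L, 3L, 3L))                  # 9: too few
  rows[[12]] <- days_grid(12L, c(5L, 5L, 2L))                  # 12: loses day 3
  rows[[13]] <- days_grid(13L, c(3L, 3L, 3L, 1L))              # 10: borderline
  rows[[14]] <- rbind(days_grid(14L, rep(5L, 7L)),             # double completion
                      mk(14L, 1L, 1L, hour_offset = 12L))
  rows[[15]] <- rbind(days_grid(15L, c(3L, 3L, 3L)),           # 9 complete
                      days_grid(15L, c(0L, 0L, 0L, 3L),
                                drop_item = "tension_stress"))
  rows[[16]] <- days_grid(16L, rep(4L, 5L))                    # 20, no metadata
  rows[[17]] <- days_grid(17L, rep(3L, 5L))                    # 15, dep missing
  rows[[18]] <- days_grid(18L, rep(3L, 6L))                    # 18
  rows[[19]] <- days_grid(19L, rep(5L, 5L))                    # 25
  rows[[20]] <- days_grid(20L, c(5L, 4L, 3L, 2L))              # 14: loses day 4
  prompts <- do.call(rbind, rows)
  rownames(prompts) <- NULL

  ids <- setdiff(1:20, 16L)                                    # P16 has no meta
  participants <- data.frame(
    participant_id = sprintf("P%02d", ids),
    age = 25L + ids,
    gender = ifelse(ids %% 2L == 1L, "f", "m"),
    stringsAsFactors = FALSE
  )
  for (j in 1:8)
    participants[[paste0("dep_", j)]] <- (ids * j) %% 5L
  for (j in 1:6)
    participants[[paste0("anx_", j)]] <- (ids * (j + 1L)) %% 5L
  participants[participants$participant_id == "P17",
               paste0("dep_", 1:8)] <- NA_integer_
  list(prompts = prompts, participants = participants)
}
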
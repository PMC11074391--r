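## Symptom-subscale scoring and elevated-status classification.
## Depression: 8 items; generalized anxiety: 6 items; each item rated
## 0..4 over the last 4 weeks; elevated status = total strictly above 11.

#' Score a symptom subscale
#'
#' Arithmetic sum of item responses, after validating item count and the
#' 0--4 response range.
#'
#' @param items Integer vector of item responses.
#' @param n_items Expected number of items (8 for depression, 6 for
#'   anxiety); `NULL` skips the length check.
#' @param max_item Maximum item response.
#' @return Integer total, or `NA` if any item is missing.
#' @examples
#' score_subscale(c(2, 1, 3, 0, 1, 2, 1, 2), n_items = 8)  # 12
#' @export
score_subscale <- function(items, n_items = NULL, max_item = 4L) {
  if (!is.null(n_items) && length(items) != n_items)
    stop("expected ", n_items, " items, got ", length(items))
  ok <- is.na(items) | (items >= 0 & items <= max_item & items == round(items))
  if (!all(ok))
    stop("item responses must be integers in 0..", max_item)
  if (anyNA(items)) return(NA_integer_)
  as.integer(sum(items))
}

#' Classify elevated symptom status
#'
#' Elevated iff the subscale total is strictly greater than the cutoff
#' (a total of exactly 11 is classified as normal).
#'
#' @param total Subscale total(s).
#' @param cutoff Cutoff score (default 11 for both subscales).
#' @return Integer vector: 1 = elevated, 0 = normal, `NA` preserved.
#' @export
classify_elevated <- function(total, cutoff = 11L) {
  ifelse(is.na(total), NA_integer_, as.integer(total > cutoff))
}

#' Score a participant table into analysis outcomes
#'
#' Accepts item-level responses (`dep_1..dep_8`, `anx_1..anx_6`) or
#' precomputed totals (`dep_total`, `anx_total`). Participants with any
#' missing item on a subscale get `NA` for that subscale (no imputation);
#' totals outside the admissible range are rejected.
#'
#' @param meta Participant table from [read_participants()].
#' @param cutoff Elevated-status cutoff applied to both subscales.
#' @return Data frame with `participant_id`, `age`, `gender`,
#'   `gender_female` (1 = female), `dep_total`, `anx_total`,
#'   `dep_elevated`, `anx_elevated`.
#' @export
score_participants <- function(meta, cutoff = 11L) {
  total_from <- function(prefix, k) {
    cols <- paste0(prefix, "_", seq_len(k))
    if (all(cols %in% names(meta))) {
      m <- as.matrix(meta[cols])
      bad <- !is.na(m) & (m < 0 | m > 4 | m != round(m))
      if (any(bad))
        stop(prefix, " item responses must be integers in 0..4")
      tot <- rowSums(m)                      # NA when any item missing
      as.integer(round(tot))
    } else if (paste0(prefix, "_total") %in% names(meta)) {
      tot <- meta[[paste0(prefix, "_total")]]
      if (any(!is.na(tot) & (tot < 0 | tot > 4 * k)))
        stop(prefix, "_total outside [0, ", 4 * k, "]")
      as.integer(tot)
    } else {
      stop("participant table needs ", prefix, "_1..", prefix, "_", k,
           " or ", prefix, "_total")
    }
  }
  dep_total <- total_from("dep", 8L)
  anx_total <- total_from("anx", 6L)
  data.frame(
    participant_id = meta$participant_id,
    age = meta$age,
    gender = meta$gender,
    gender_female = as.integer(meta$gender == "f"),
    dep_total = dep_total,
    anx_total = anx_total,
    dep_elevated = classify_elevated(dep_total, cutoff),
    anx_elevated = classify_elevated(anx_total, cutoff),
    stringsAsFactors = FALSE
  )
}

#' Prevalence of elevated symptoms and depression/anxiety overlap
#'
#' Prevalence is computed per subscale over participants with a known
#' status on that subscale. The overlap block is computed among the union
#' of participants elevated on either subscale, restricted to those with
#' both statuses known. Percentages are rounded to 1 decimal place.
#'
#' @param outcomes Outcomes from [score_participants()] (columns
#'   `dep_elevated`, `anx_elevated`; `NA` allowed).
#' @return A list of counts (`n`, `n_dep_known`, `n_anx_known`, `n_dep`,
#'   `n_anx`, `n_union`, `n_both`, `n_dep_only`, `n_anx_only`) and
#'   percentages (`pct_dep`, `pct_anx`, `pct_both`, `pct_dep_only`,
#'   `pct_anx_only`).
#' @export
prevalence_and_overlap <- function(outcomes) {
  dep <- outcomes$dep_elevated
  anx <- outcomes$anx_elevated
  pct <- function(num, den) if (den > 0) round(100 * num / den, 1) else 0
  n_dep_known <- sum(!is.na(dep))
  n_anx_known <- sum(!is.na(anx))
  n_dep <- sum(dep == 1L, na.rm = TRUE)
  n_anx <- sum(anx == 1L, na.rm = TRUE)
  both_known <- !is.na(dep) & !is.na(anx)
  n_both <- sum(both_known & dep == 1L & anx == 1L)
  n_dep_only <- sum(both_known & dep == 1L & anx == 0L)
  n_anx_only <- sum(both_known & dep == 0L & anx == 1L)
  n_union <- n_both + n_dep_only + n_anx_only
  list(
    n = nrow(outcomes),
    n_dep_known = n_dep_known, n_anx_known = n_anx_known,
    n_dep = n_dep, n_anx = n_anx,
    n_union = n_union, n_both = n_both,
    n_dep_only = n_dep_only, n_anx_only = n_anx_only,
    pct_dep = pct(n_dep, n_dep_known),
    pct_anx = pct(n_anx, n_anx_known),
    pct_both = pct(n_both, n_union),
    pct_dep_only = pct(n_dep_only, n_union),
    pct_anx_only = pct(n_anx_only, n_union)
  )
}
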
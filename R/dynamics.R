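## Per-person emotion-dynamics indices: intensity (mean of daily means),
## instability (mean of daily RMSSDs), inertia (lag-1 autocorrelation with
## day breaks, Fisher-z), and differentiation (average Fisher-z pairwise
## correlation between same-valence item series; higher = poorer
## differentiation).

#' Fisher z-transform of a correlation
#'
#' `atanh(r)`, with inputs clamped to +/-(1 - 1e-7) so that perfectly
#' coupled series yield a large finite value instead of an infinity that
#' would propagate into regression models.
#'
#' @param r Correlation coefficient(s) in \[-1, 1\]; `NA` passes through.
#' @param clamp Magnitude at which `|r|` is clamped before the transform.
#' @return Numeric vector of z values.
#' @examples
#' fisher_z(0.5)   # 0.5493
#' fisher_z(-0.5)  # antisymmetric
#' @export
fisher_z <- function(r, clamp = 1 - 1e-7) {
  atanh(pmin(pmax(r, -clamp), clamp))
}

#' Root mean squared successive differences of one day's affect series
#'
#' `sqrt(mean((x[t+1] - x[t])^2))` over successive answered prompts within
#' a day. By default a skipped middle slot does not split the day: the
#' differences are taken between consecutive *answered* prompts. With
#' `strict_adjacent = TRUE` only pairs in adjacent scheduled slots count.
#'
#' @param x One day's prompt-level affect means in slot order; `NA` marks
#'   an unanswered slot.
#' @param strict_adjacent Restrict successive pairs to adjacent slots.
#' @return Non-negative number, or `NA` when fewer than two usable
#'   observations (no successive pair) exist.
#' @examples
#' rmssd(c(2, 2, 2))       # 0
#' rmssd(c(0, 2, 1, 3))    # sqrt(3)
#' rmssd(5)                # NA
#' @export
rmssd <- function(x, strict_adjacent = FALSE) {
  if (strict_adjacent) {
    d <- diff(x)
    d <- d[!is.na(d)]
  } else {
    v <- x[!is.na(x)]
    if (length(v) < 2L) return(NA_real_)
    d <- diff(v)
  }
  if (length(d) == 0L) return(NA_real_)
  sqrt(mean(d^2))
}

#' Lag-1 autocorrelation of a week's affect series with day breaks
#'
#' Estimates the average within-day lag-1 autocorrelation across the study
#' period. A break is inserted after the last observation of each day, so
#' lagged pairs `(x[t], x[t+1])` are formed only for consecutive answered
#' prompts within the same day; the last prompt of one day is never paired
#' with the first prompt of the next. The estimate is the Pearson
#' correlation between the lead and lag columns over all such pairs (on a
#' gap-free single day this reduces to the textbook lag-1 autocorrelation
#' `cor(x[-n], x[-1])`).
#'
#' @param x The participant's prompt-level affect means in chronological
#'   order (answered prompts only).
#' @param day Day label for each element of `x`.
#' @param slot Optional slot index per element; only used when
#'   `strict_adjacent = TRUE`.
#' @param min_pairs Minimum number of lagged pairs required; fewer yields
#'   `NA` (a correlation on fewer than 3 points is degenerate).
#' @param strict_adjacent Restrict pairs to adjacent scheduled slots.
#' @return Correlation in \[-1, 1\], or `NA` when there are fewer than
#'   `min_pairs` pairs or either pair column has zero variance.
#' @examples
#' lag1_autocor(c(1, 2, 3, 4, 5), day = rep(1, 5))          # 1
#' lag1_autocor(c(1, 2, 3, 10, 11, 12), day = rep(1:2, each = 3))
#' @export
lag1_autocor <- function(x, day, slot = NULL, min_pairs = 3L,
                         strict_adjacent = FALSE) {
  n <- length(x)
  if (n < 2L) return(NA_real_)
  same <- day[-1] == day[-n]
  if (strict_adjacent) {
    if (is.null(slot)) stop("slot is required when strict_adjacent = TRUE")
    same <- same & (slot[-1] - slot[-n] == 1L)
  }
  lead <- x[-n][same]
  lag <- x[-1][same]
  if (length(lead) < min_pairs) return(NA_real_)
  if (stats::var(lead) < 1e-10 || stats::var(lag) < 1e-10) return(NA_real_)
  stats::cor(lead, lag)
}

pairwise_fisher_z <- function(mat, min_obs = 3L) {
  # mean Fisher-z of all pairwise Pearson correlations between columns;
  # zero-variance pairs are skipped, NA when no pair is computable
  k <- ncol(mat)
  zs <- c()
  for (i in seq_len(k - 1L)) {
    for (j in seq.int(i + 1L, k)) {
      ok <- !is.na(mat[, i]) & !is.na(mat[, j])
      if (sum(ok) < min_obs) next
      xi <- mat[ok, i]
      xj <- mat[ok, j]
      if (stats::var(xi) < 1e-10 || stats::var(xj) < 1e-10) next
      zs <- c(zs, fisher_z(stats::cor(xi, xj)))
    }
  }
  if (length(zs) == 0L) NA_real_ else mean(zs)
}

#' Negative-affect differentiation index
#'
#' Mean of the Fisher z-transformed Pearson correlations between all 6
#' pairs of the 4 NA item series over a participant's answered prompts.
#' Higher values indicate poorer emotional differentiation. Pairs
#' involving a zero-variance series are skipped; `NA` when no pair is
#' computable.
#'
#' @param mat Numeric matrix with one column per NA item and one row per
#'   answered prompt.
#' @param min_obs Minimum paired observations per correlation.
#' @return Mean Fisher-z correlation, or `NA`.
#' @export
na_differentiation <- function(mat, min_obs = 3L) {
  stopifnot(ncol(mat) >= 2L)
  pairwise_fisher_z(as.matrix(mat), min_obs = min_obs)
}

#' Positive-affect differentiation index
#'
#' Fisher z-transformed Pearson correlation between the two PA item
#' series over a participant's answered prompts. Higher values indicate
#' poorer differentiation. `NA` when either series has zero variance.
#'
#' @param x1,x2 The two PA item series (paired by prompt).
#' @param min_obs Minimum paired observations.
#' @return Fisher-z correlation, or `NA`.
#' @export
pa_differentiation <- function(x1, x2, min_obs = 3L) {
  pairwise_fisher_z(cbind(x1, x2), min_obs = min_obs)
}

## ---- vectorized cohort-level computation ------------------------------

group_stats <- function(x, g, nlev) {
  # group means by integer level codes; NA where a level has no rows
  s <- rowsum(x, g)
  cnt <- rowsum(rep(1, length(x)), g)
  out <- rep(NA_real_, nlev)
  out[as.integer(rownames(s))] <- s[, 1L] / cnt[, 1L]
  out
}

pearson_by_group <- function(x, y, g, nlev, min_pairs = 3L) {
  # per-group Pearson correlation from moment sums; NA for groups with
  # too few pairs or (near-)zero variance in either column
  out <- rep(NA_real_, nlev)
  if (length(x) == 0L) return(out)
  s <- rowsum(cbind(1, x, y, x * x, y * y, x * y), g)
  idx <- as.integer(rownames(s))
  n <- s[, 1L]
  vx <- s[, 4L] - s[, 2L]^2 / n
  vy <- s[, 5L] - s[, 3L]^2 / n
  cxy <- s[, 6L] - s[, 2L] * s[, 3L] / n
  r <- ifelse(n >= min_pairs & vx > 1e-10 & vy > 1e-10,
              cxy / sqrt(vx * vy), NA_real_)
  out[idx] <- r
  out
}

#' Compute all emotion-dynamics indices for a filtered cohort
#'
#' One row per participant with the eight indices: PA/NA intensity (mean
#' over days of the daily mean of prompt-level affect means), PA/NA
#' instability (mean over days of the daily RMSSD, skipping days without a
#' successive pair), PA/NA inertia (Fisher-z lag-1 autocorrelation with
#' day breaks; [lag1_autocor()]), and PA/NA differentiation (Fisher-z
#' correlation summaries; [pa_differentiation()], [na_differentiation()]).
#' Intensity and instability deliberately average day-level values, not
#' prompts, so days with unequal prompt counts carry equal weight.
#'
#' The computation is vectorized over the whole cohort but is exactly
#' equivalent to applying the per-person functions participant by
#' participant.
#'
#' @param records Selection-filtered prompt records (complete prompts,
#'   unique keys).
#' @param design An [ema_design()].
#' @param min_lag_pairs Minimum lagged pairs for the inertia estimate.
#' @param strict_adjacent Restrict successive/lagged pairs to adjacent
#'   scheduled slots (see [rmssd()]).
#' @return Data frame with columns `participant_id`, `pa_intensity`,
#'   `na_intensity`, `pa_instability`, `na_instability`, `pa_inertia_z`,
#'   `na_inertia_z`, `pa_diff_z`, `na_diff_z`, `n_prompts`, `n_days`.
#' @export
compute_profiles <- function(records, design = ema_design(),
                             min_lag_pairs = 3L, strict_adjacent = FALSE) {
  cols <- c("participant_id", "pa_intensity", "na_intensity",
            "pa_instability", "na_instability", "pa_inertia_z",
            "na_inertia_z", "pa_diff_z", "na_diff_z", "n_prompts", "n_days")
  if (nrow(records) == 0L) {
    out <- data.frame(participant_id = character(0))
    for (cl in cols[-1L]) out[[cl]] <- numeric(0)
    return(out)
  }
  records <- records[order(records$participant_id, records$day,
                           records$slot), , drop = FALSE]
  records <- prompt_affect_means(records, design)
  pid <- factor(records$participant_id,
                levels = unique(records$participant_id))
  p <- as.integer(pid)
  nlev <- nlevels(pid)
  n <- nrow(records)

  # participant-day run ids (rows are sorted)
  newday <- c(TRUE, p[-1L] != p[-n] | records$day[-1L] != records$day[-n])
  did <- cumsum(newday)
  day_p <- p[newday]
  nday <- max(did)

  # intensity: daily means, then mean over days
  pa_day <- group_stats(records$pa_mean, did, nday)
  na_day <- group_stats(records$na_mean, did, nday)
  pa_intensity <- group_stats(pa_day, day_p, nlev)
  na_intensity <- group_stats(na_day, day_p, nlev)

  # successive pairs within a participant-day
  same <- did[-1L] == did[-n]
  if (strict_adjacent)
    same <- same & (records$slot[-1L] - records$slot[-n] == 1L)

  d_pa <- diff(records$pa_mean)[same]
  d_na <- diff(records$na_mean)[same]
  d_did <- did[-1L][same]
  rmssd_pa_day <- sqrt(group_stats(d_pa^2, d_did, nday))
  rmssd_na_day <- sqrt(group_stats(d_na^2, d_did, nday))
  has_rmssd <- !is.na(rmssd_pa_day)
  pa_instability <- group_stats(rmssd_pa_day[has_rmssd],
                                day_p[has_rmssd], nlev)
  na_instability <- group_stats(rmssd_na_day[has_rmssd],
                                day_p[has_rmssd], nlev)

  # inertia: Pearson over within-day lagged pairs, pooled per participant
  g <- p[-1L][same]
  pa_inertia_z <- fisher_z(pearson_by_group(
    records$pa_mean[-n][same], records$pa_mean[-1L][same],
    g, nlev, min_pairs = min_lag_pairs))
  na_inertia_z <- fisher_z(pearson_by_group(
    records$na_mean[-n][same], records$na_mean[-1L][same],
    g, nlev, min_pairs = min_lag_pairs))

  # differentiation: pairwise item correlations over all answered prompts
  mean_pair_z <- function(items) {
    k <- length(items)
    zsum <- rep(0, nlev)
    zcnt <- rep(0L, nlev)
    for (i in seq_len(k - 1L)) {
      for (j in seq.int(i + 1L, k)) {
        r <- pearson_by_group(records[[items[i]]], records[[items[j]]],
                              p, nlev, min_pairs = 3L)
        ok <- !is.na(r)
        zsum[ok] <- zsum[ok] + fisher_z(r[ok])
        zcnt[ok] <- zcnt[ok] + 1L
      }
    }
    ifelse(zcnt > 0L, zsum / zcnt, NA_real_)
  }
  pa_diff_z <- mean_pair_z(design$pa_items)
  na_diff_z <- mean_pair_z(design$na_items)

  data.frame(
    participant_id = levels(pid),
    pa_intensity = pa_intensity,
    na_intensity = na_intensity,
    pa_instability = pa_instability,
    na_instability = na_instability,
    pa_inertia_z = pa_inertia_z,
    na_inertia_z = na_inertia_z,
    pa_diff_z = pa_diff_z,
    na_diff_z = na_diff_z,
    n_prompts = tabulate(p, nlev),
    n_days = tabulate(day_p, nlev),
    stringsAsFactors = FALSE
  )
}
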
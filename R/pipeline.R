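## End-to-end orchestration: selection -> screening -> dynamics -> models,
## with rendered analogues of the four standard report tables
## (sample descriptives, group comparisons, individual-index odds ratios,
## initial/final joint models).

#' Pipeline configuration
#'
#' Bundles every tunable of the analysis chain. The defaults are the
#' reference configuration of the package: a 7x5 design with the
#' 10/3/3 compliance filters, subscale cutoff 11, NA instability promoted
#' into the final model, and a 0.01 significance level with 99 percent CIs.
#'
#' @param design An [ema_design()].
#' @param cutoff Elevated-status cutoff for both subscales.
#' @param promote Index (or indices, or `"auto"`) added to the final
#'   joint model; see [run_joint_models()].
#' @param alpha Significance threshold.
#' @param conf_level Confidence level for all intervals.
#' @param min_lag_pairs Minimum lagged pairs for the inertia index.
#' @param strict_adjacent Restrict successive pairs to adjacent slots.
#' @param seed Optional seed recorded with the run.
#' @return A list of class `"pipeline_config"`; serializable with
#'   [write_pipeline_config()].
#' @export
pipeline_config <- function(design = ema_design(),
                            cutoff = 11L,
                            promote = "na_instability",
                            alpha = 0.01,
                            conf_level = 0.99,
                            min_lag_pairs = 3L,
                            strict_adjacent = FALSE,
                            seed = NULL) {
  structure(
    list(design = design, cutoff = as.integer(cutoff), promote = promote,
         alpha = alpha, conf_level = conf_level,
         min_lag_pairs = as.integer(min_lag_pairs),
         strict_adjacent = isTRUE(strict_adjacent), seed = seed),
    class = "pipeline_config"
  )
}

#' Write / read a pipeline configuration as JSON
#'
#' The JSON round trip reproduces the configuration exactly.
#'
#' @param config A [pipeline_config()].
#' @param path JSON file path.
#' @return `write_pipeline_config()` returns `path` invisibly;
#'   `read_pipeline_config()` returns the configuration.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  x <- unclass(config)
  x$design <- unclass(x$design)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  design <- do.call(ema_design, x$design)
  pipeline_config(
    design = design, cutoff = x$cutoff, promote = x$promote,
    alpha = x$alpha, conf_level = x$conf_level,
    min_lag_pairs = x$min_lag_pairs, strict_adjacent = x$strict_adjacent,
    seed = x$seed
  )
}

table1_descriptives <- function(data) {
  block <- function(oc, label) {
    flag <- data[[oc]]
    out <- lapply(c(normal = 0L, elevated = 1L), function(v) {
      g <- data[!is.na(flag) & flag == v, , drop = FALSE]
      data.frame(
        outcome = label, group = if (v == 0L) "normal" else "elevated",
        n = nrow(g),
        pct = round(100 * nrow(g) / sum(!is.na(flag)), 1),
        age_mean = round(mean(g$age), 2), age_sd = round(stats::sd(g$age), 2),
        n_women = sum(g$gender_female == 1L),
        n_men = sum(g$gender_female == 0L),
        stringsAsFactors = FALSE
      )
    })
    do.call(rbind, out)
  }
  rbind(block("dep_elevated", "depression"), block("anx_elevated", "anxiety"))
}

table2_group_comparisons <- function(data,
                                     indices = index_names()) {
  rows <- list()
  for (oc in c("dep_elevated", "anx_elevated")) {
    for (ix in indices) {
      ok <- !is.na(data[[oc]]) & !is.na(data[[ix]])
      x0 <- data[[ix]][ok & data[[oc]] == 0L]
      x1 <- data[[ix]][ok & data[[oc]] == 1L]
      res <- if (length(x0) >= 2L && length(x1) >= 2L &&
                 (stats::sd(x0) > 0 || stats::sd(x1) > 0))
        welch_t(mean(x0), stats::sd(x0), length(x0),
                mean(x1), stats::sd(x1), length(x1))
      else list(t = NA_real_, df = NA_real_, p = NA_real_)
      rows[[length(rows) + 1L]] <- data.frame(
        outcome = if (oc == "dep_elevated") "depression" else "anxiety",
        index = ix,
        m_normal = round(mean(x0), 2), sd_normal = round(stats::sd(x0), 2),
        n_normal = length(x0),
        m_elevated = round(mean(x1), 2),
        sd_elevated = round(stats::sd(x1), 2),
        n_elevated = length(x1),
        t = round(res$t, 2), p = round(res$p, 4),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

table4_joint <- function(joint) {
  rows <- list()
  for (oc in names(joint)) {
    for (model in c("initial", "final")) {
      f <- joint[[oc]][[model]]
      t <- f$terms
      rows[[length(rows) + 1L]] <- data.frame(
        outcome = oc, model = model, n = f$n_used, term = t$term,
        b = round(t$b, 2), se = round(t$se, 2), z = round(t$z, 2),
        p = round(t$p, 4), or = round(t$or, 2),
        ci_lo = round(t$ci_lo, 2), ci_hi = round(t$ci_hi, 2),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

comparison_table <- function(joint) {
  do.call(rbind, lapply(names(joint), function(oc) {
    cmp <- joint[[oc]]$comparison
    data.frame(
      outcome = oc,
      chi2 = round(cmp$chi2, 2), df = cmp$df, p = round(cmp$p, 4),
      aic_initial = round(joint[[oc]]$initial$aic, 2),
      aic_final = round(joint[[oc]]$final$aic, 2),
      pseudo_r2_adj_initial = round(joint[[oc]]$initial$pseudo_r2_adjusted, 2),
      pseudo_r2_adj_final = round(joint[[oc]]$final$pseudo_r2_adjusted, 2),
      stringsAsFactors = FALSE
    )
  }))
}

#' Run the full analysis pipeline
#'
#' Validation and data selection, subscale scoring, emotion-dynamics
#' indices, group comparisons, individual and joint logistic models, and
#' the parallel linear models, with a retention log covering every stage.
#' An analysis set that ends up empty (or an outcome with a single class)
#' is reported gracefully: the corresponding model slots are `NULL` and
#' `note` says why.
#'
#' @param prompts Long-format prompt records (see [read_ema_long()]).
#' @param participants Participant table (see [read_participants()]).
#' @param config A [pipeline_config()].
#' @return A list of class `"affectdyn_results"`: `retention`,
#'   `profiles`, `outcomes`, `analysis` (joined per-participant data),
#'   `prevalence`, `table1`, `table2`, `table3`, `table4`, `comparisons`,
#'   `individual`, `joint`, `linear`, `config`, `note`.
#' @export
run_pipeline <- function(prompts, participants,
                         config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  design <- config$design
  sel <- preprocess_ema(prompts, design)
  outcomes <- score_participants(participants, cutoff = config$cutoff)
  joined <- join_outcomes(sel$records, outcomes)
  sel$retention <- rbind(sel$retention,
                         retention_row("with_outcomes", joined$records))

  res <- list(retention = sel$retention, outcomes = joined$outcomes,
              config = config, note = NULL)
  if (nrow(joined$records) == 0L) {
    res$note <- "analysis set is empty after selection"
    res$profiles <- compute_profiles(joined$records, design)
    res$analysis <- res$profiles
    class(res) <- "affectdyn_results"
    return(res)
  }

  profiles <- compute_profiles(joined$records, design,
                               min_lag_pairs = config$min_lag_pairs,
                               strict_adjacent = config$strict_adjacent)
  analysis <- merge(profiles, joined$outcomes, by = "participant_id",
                    sort = TRUE)
  res$profiles <- profiles
  res$analysis <- analysis
  res$prevalence <- prevalence_and_overlap(analysis)
  res$table1 <- table1_descriptives(analysis)
  res$table2 <- table2_group_comparisons(analysis)

  two_classes <- function(oc) {
    v <- analysis[[oc]]
    length(unique(v[!is.na(v)])) == 2L
  }
  ocs <- c("dep_elevated", "anx_elevated")[
    vapply(c("dep_elevated", "anx_elevated"), two_classes, logical(1))]
  if (length(ocs) == 0L) {
    res$note <- "no outcome with both classes; models skipped"
  } else {
    res$individual <- run_individual_models(
      analysis, outcomes = ocs, conf_level = config$conf_level)
    res$table3 <- res$individual$table
    res$table3[c("b", "se", "z", "or", "ci_lo", "ci_hi")] <-
      round(res$table3[c("b", "se", "z", "or", "ci_lo", "ci_hi")], 2)
    res$table3$p <- round(res$table3$p, 4)
    res$joint <- run_joint_models(
      analysis, outcomes = ocs, promote = config$promote,
      alpha = config$alpha, conf_level = config$conf_level)
    res$table4 <- table4_joint(res$joint)
    res$comparisons <- comparison_table(res$joint)
    lin_ocs <- c(dep_elevated = "dep_total",
                 anx_elevated = "anx_total")[ocs]
    promote_lin <- if (identical(config$promote, "auto"))
      "na_instability" else config$promote
    res$linear <- run_linear_models(analysis, outcomes = unname(lin_ocs),
                                    promote = promote_lin)
  }
  class(res) <- "affectdyn_results"
  res
}

#' @export
print.affectdyn_results <- function(x, ...) {
  cat("EMA affect-dynamics analysis\n")
  print(x$retention, row.names = FALSE)
  if (!is.null(x$note)) cat("note:", x$note, "\n")
  if (!is.null(x$prevalence))
    cat(sprintf("elevated depression %.1f%%, elevated anxiety %.1f%%\n",
                x$prevalence$pct_dep, x$prevalence$pct_anx))
  if (!is.null(x$comparisons)) {
    cat("initial vs final model comparisons:\n")
    print(x$comparisons, row.names = FALSE)
  }
  invisible(x)
}

#' Write the rendered result tables to CSV
#'
#' Writes the retention log, per-participant profiles, and the four
#' rendered tables (descriptives, group comparisons, individual-index
#' odds ratios, joint models plus their comparisons). Descriptives and
#' ORs are rounded to 2 decimals, p-values to 4; the unrounded values
#' remain available in the results object. Empty result slots produce
#' header-only files.
#'
#' @param results An [run_pipeline()] result.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
render_tables <- function(results, dir) {
  stopifnot(inherits(results, "affectdyn_results"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  w <- function(x, name) {
    if (is.null(x))
      x <- data.frame()
    utils::write.csv(x, file.path(dir, name), row.names = FALSE, na = "")
  }
  w(results$retention, "retention.csv")
  w(results$profiles, "profiles.csv")
  w(results$table1, "table1_descriptives.csv")
  w(results$table2, "table2_group_comparisons.csv")
  w(results$table3, "table3_individual_or.csv")
  w(results$table4, "table4_joint_models.csv")
  w(results$comparisons, "model_comparisons.csv")
  invisible(dir)
}
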
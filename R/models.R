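## Statistical layer: Welch t group comparisons, covariate-adjusted
## logistic models for elevated symptom status with odds ratios and 99%
## Wald CIs, nested model comparison (likelihood-ratio test, AIC,
## adjusted McFadden pseudo-R2), and the parallel linear models.

#' Standardize a variable to z-scores
#'
#' Centers and scales to mean 0 and sample SD 1 (n-1 denominator),
#' computed over non-missing values; missing values are preserved.
#' Predictors are standardized on the listwise-complete analysis sample
#' of the model at hand (see [fit_logistic()]).
#'
#' @param x Numeric vector with at least 2 non-missing values and
#'   nonzero variance.
#' @return z-scores with the same length (and missingness) as `x`.
#' @export
standardize <- function(x) {
  label <- deparse(substitute(x))
  v <- x[!is.na(x)]
  if (length(v) < 2L)
    stop("standardize needs >= 2 non-missing values in ", label)
  s <- stats::sd(v)
  if (s == 0)
    stop("zero variance in ", label)
  (x - mean(v)) / s
}

#' Welch two-sample t-test from group summaries
#'
#' Unequal-variance t statistic with Welch--Satterthwaite degrees of
#' freedom and a two-sided p-value, computed from group means, SDs and
#' sizes (so printed descriptive tables can be re-tested directly).
#'
#' @param m1,sd1,n1 Mean, SD and size of group 1.
#' @param m2,sd2,n2 Mean, SD and size of group 2.
#' @return A list of class `"welch_t"`: the inputs plus `t`, `df`, `p`.
#' @examples
#' welch_t(0.57, 0.57, 167, 1.72, 0.96, 52)$t  # about -8.20
#' @export
welch_t <- function(m1, sd1, n1, m2, sd2, n2) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  if (sd1 == 0 && sd2 == 0)
    stop("both group SDs are zero; t is undefined")
  v1 <- sd1^2 / n1
  v2 <- sd2^2 / n2
  se <- sqrt(v1 + v2)
  t <- (m1 - m2) / se
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  structure(
    list(m1 = m1, sd1 = sd1, n1 = n1, m2 = m2, sd2 = sd2, n2 = n2,
         t = t, df = df, p = 2 * stats::pt(-abs(t), df)),
    class = "welch_t"
  )
}

#' @export
print.welch_t <- function(x, ...) {
  cat(sprintf("Welch t = %.2f, df = %.1f, p = %.4g\n", x$t, x$df, x$p))
  invisible(x)
}

#' Odds ratio with Wald confidence interval from a log-odds coefficient
#'
#' `OR = exp(B)` with interval `exp(B -/+ z * SE)` where `z` is the
#' standard-normal quantile for the requested confidence level
#' (2.5758 at the 99 percent level).
#'
#' @param b Log-odds coefficient(s).
#' @param se Standard error(s); must be positive.
#' @param conf_level Confidence level (default 0.99).
#' @return Data frame with columns `or`, `lo`, `hi`.
#' @examples
#' or_ci99(0.77, 0.27)  # OR about 2.16
#' @export
or_ci99 <- function(b, se, conf_level = 0.99) {
  stopifnot(all(se > 0))
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  data.frame(or = exp(b), lo = exp(b - zq * se), hi = exp(b + zq * se))
}

#' Covariate-adjusted binary logistic regression
#'
#' Maximum-likelihood logistic regression of a binary elevated-symptom
#' outcome (0 = normal, 1 = elevated) on one or more emotion-dynamics
#' predictors plus covariates. Rows are selected by listwise deletion
#' over the model's variables; predictors (but not covariates) are then
#' standardized on those rows, so the covariates age (years) and gender
#' (female = 1) keep their natural units. Reported per term: B, SE, Wald
#' z and p, OR and Wald CI; plus log-likelihood, AIC, and McFadden
#' pseudo-R2 (plain and adjusted) against the intercept-only model on the
#' same rows.
#'
#' @param data Data frame holding outcome, predictors and covariates.
#' @param outcome Name of the 0/1 outcome column; both classes must occur.
#' @param predictors Character vector of predictor columns (standardized).
#' @param covariates Character vector of covariate columns (left on their
#'   raw scale); default age and gender_female.
#' @param standardize_predictors Set `FALSE` to keep predictors raw.
#' @param conf_level Confidence level for the Wald intervals.
#' @return An object of class `"logistic_fit"`: `terms` (coefficient
#'   table), `n_used`, `rows` (ids of the analysis rows), `ll`, `ll_null`,
#'   `k`, `aic`, `pseudo_r2_mcfadden`, `pseudo_r2_adjusted`, `separation`.
#' @export
fit_logistic <- function(data, outcome, predictors,
                         covariates = c("age", "gender_female"),
                         standardize_predictors = TRUE,
                         conf_level = 0.99) {
  vars <- c(outcome, predictors, covariates)
  missing_cols <- setdiff(vars, names(data))
  if (length(missing_cols) > 0L)
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  rows <- which(stats::complete.cases(data[vars]))
  d <- data[rows, vars, drop = FALSE]
  y <- d[[outcome]]
  if (!all(y %in% c(0L, 1L)))
    stop("outcome must be coded 0/1")
  if (length(unique(y)) < 2L)
    stop("outcome '", outcome, "' has a single class on the analysis rows")
  if (standardize_predictors) {
    for (v in predictors) {
      s <- stats::sd(d[[v]])
      if (is.na(s) || s == 0) stop("zero variance in predictor ", v)
      d[[v]] <- (d[[v]] - mean(d[[v]])) / s
    }
  }
  labs <- c(predictors, covariates)
  fmla <- if (length(labs) == 0L)
    stats::as.formula(paste(outcome, "~ 1")) else
    stats::reformulate(labs, response = outcome)
  fit <- stats::glm(fmla, data = d, family = stats::binomial())
  co <- summary(fit)$coefficients
  ci <- or_ci99(co[, 1L], co[, 2L], conf_level = conf_level)
  terms <- data.frame(
    term = rownames(co),
    b = co[, 1L], se = co[, 2L], z = co[, 3L], p = co[, 4L],
    or = ci$or, ci_lo = ci$lo, ci_hi = ci$hi,
    row.names = NULL, stringsAsFactors = FALSE
  )
  ll <- as.numeric(stats::logLik(fit))
  k <- length(stats::coef(fit))
  null_fit <- stats::glm(y ~ 1, family = stats::binomial())
  ll0 <- as.numeric(stats::logLik(null_fit))
  separation <- !fit$converged || any(abs(co[, 1L]) > 15) || any(co[, 2L] > 50)
  if (separation)
    warning("possible separation or non-convergence in model for '",
            outcome, "'")
  ids <- if ("participant_id" %in% names(data))
    data$participant_id[rows] else rownames(data)[rows]
  structure(
    list(
      outcome = outcome,
      predictors = predictors,
      covariates = covariates,
      terms = terms,
      n_used = nrow(d),
      rows = ids,
      ll = ll,
      ll_null = ll0,
      k = k,
      aic = 2 * k - 2 * ll,
      pseudo_r2_mcfadden = 1 - ll / ll0,
      pseudo_r2_adjusted = 1 - (ll - (k - 1L)) / ll0,
      conf_level = conf_level,
      separation = separation
    ),
    class = "logistic_fit"
  )
}

#' @export
print.logistic_fit <- function(x, digits = 3, ...) {
  cat("Logistic model for", x$outcome, " (n =", x$n_used, ")\n")
  tab <- x$terms
  tab[-1L] <- lapply(tab[-1L], round, digits)
  print(tab, row.names = FALSE)
  cat(sprintf(
    "logLik = %.2f, AIC = %.2f, pseudo-R2 = %.3f (adjusted %.3f)\n",
    x$ll, x$aic, x$pseudo_r2_mcfadden, x$pseudo_r2_adjusted))
  if (x$separation) cat("warning: possible separation\n")
  invisible(x)
}

#' Adjusted McFadden pseudo-R-squared
#'
#' `1 - (LL_model - k_extra) / LL_null`, where `k_extra` is the number of
#' non-intercept parameters; the penalty makes the measure decrease in
#' expectation when pure-noise predictors are added. The null model is
#' the intercept-only fit on the same rows.
#'
#' @param fit A [fit_logistic()] object (which stores its own null
#'   log-likelihood), or a log-likelihood value if `ll_null` is given.
#' @param ll_null Optional null-model log-likelihood when `fit` is a
#'   bare log-likelihood; ignored for `"logistic_fit"` input.
#' @param k_extra Number of non-intercept parameters (bare-input form).
#' @return The adjusted pseudo-R2.
#' @export
pseudo_r2_adjusted <- function(fit, ll_null = NULL, k_extra = NULL) {
  if (inherits(fit, "logistic_fit")) {
    ll <- fit$ll
    ll_null <- fit$ll_null
    k_extra <- fit$k - 1L
  } else {
    ll <- fit
    if (is.null(ll_null) || is.null(k_extra))
      stop("ll_null and k_extra are required for bare log-likelihood input")
  }
  if (ll_null == 0)
    stop("null log-likelihood is zero; pseudo-R2 undefined")
  1 - (ll - k_extra) / ll_null
}

#' Likelihood-ratio comparison of nested logistic models
#'
#' Compares an initial model with a final model that adds predictors,
#' fitted on the identical row set. Returns the likelihood-ratio
#' chi-square `2 * (LL_final - LL_initial)`, its degrees of freedom
#' (parameter-count difference), the chi-square p-value, and the AIC
#' difference `AIC_final - AIC_initial` (negative favours the final
#' model; algebraically `2 * df - chi2`).
#'
#' @param initial,final Nested [fit_logistic()] objects; the final
#'   model's terms must contain the initial model's, and both must be
#'   fitted on the same rows.
#' @return A list of class `"model_comparison"`: `chi2`, `df`, `p`,
#'   `delta_aic`.
#' @export
lr_compare <- function(initial, final) {
  stopifnot(inherits(initial, "logistic_fit"), inherits(final, "logistic_fit"))
  if (initial$n_used != final$n_used ||
      !setequal(initial$rows, final$rows))
    stop("models were fitted on different rows; refit the initial model ",
         "on the final model's listwise-complete rows")
  if (!all(initial$terms$term %in% final$terms$term))
    stop("models are not nested: initial terms must be a subset of final")
  chi2 <- 2 * (final$ll - initial$ll)
  df <- final$k - initial$k
  structure(
    list(
      chi2 = chi2,
      df = df,
      p = if (df > 0) stats::pchisq(chi2, df, lower.tail = FALSE)
          else NA_real_,
      delta_aic = final$aic - initial$aic
    ),
    class = "model_comparison"
  )
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("LR test: chi2 = %.2f, df = %d, p = %.4g; delta AIC = %.2f\n",
              x$chi2, x$df, x$p, x$delta_aic))
  invisible(x)
}

index_names <- function() {
  c("pa_intensity", "na_intensity", "pa_instability", "na_instability",
    "pa_inertia_z", "na_inertia_z", "pa_diff_z", "na_diff_z")
}

#' Individual-predictor logistic models for every emotion-dynamics index
#'
#' For each index and each outcome, fits
#' `outcome ~ index(standardized) + age + gender` with listwise deletion
#' per model, and collects the index term's OR, CI and p into one tidy
#' table (8 indices x 2 outcomes = 16 rows by default).
#'
#' @param data Joined profiles + outcomes (one row per participant).
#' @param indices Index columns to test.
#' @param outcomes Binary outcome columns.
#' @inheritParams fit_logistic
#' @return A list: `fits` (nested list, `fits[[outcome]][[index]]`) and
#'   `table` (tidy data frame of the index terms).
#' @export
run_individual_models <- function(data,
                                  indices = index_names(),
                                  outcomes = c("dep_elevated",
                                               "anx_elevated"),
                                  covariates = c("age", "gender_female"),
                                  conf_level = 0.99) {
  fits <- list()
  rows <- list()
  for (oc in outcomes) {
    fits[[oc]] <- list()
    for (ix in indices) {
      f <- fit_logistic(data, oc, ix, covariates = covariates,
                        conf_level = conf_level)
      fits[[oc]][[ix]] <- f
      tr <- f$terms[f$terms$term == ix, , drop = FALSE]
      rows[[length(rows) + 1L]] <- data.frame(
        outcome = oc, index = ix, n = f$n_used,
        tr[c("b", "se", "z", "p", "or", "ci_lo", "ci_hi")],
        row.names = NULL, stringsAsFactors = FALSE
      )
    }
  }
  list(fits = fits, table = do.call(rbind, rows))
}

#' Initial and final joint logistic models with nested comparison
#'
#' For each outcome fits the initial model
#' `{PA intensity, NA intensity, age, gender}` and the final model adding
#' the promoted index (NA instability by default). Both models are fitted
#' on the final model's listwise-complete rows so the likelihood-ratio
#' test is valid, and compared by LR chi-square, AIC, and adjusted
#' pseudo-R2. With `promote = "auto"` the promoted set is every
#' non-base index whose individual model (see
#' [run_individual_models()]) is significant at `alpha` for that outcome.
#'
#' @param data Joined profiles + outcomes.
#' @param outcomes Binary outcome columns.
#' @param base_predictors Predictors of the initial model.
#' @param promote Character vector of indices to add in the final model,
#'   or `"auto"`.
#' @param alpha Significance threshold used by `promote = "auto"`.
#' @inheritParams fit_logistic
#' @return A list per outcome with elements `initial`, `final`
#'   ([fit_logistic()] objects), `comparison` ([lr_compare()]) and
#'   `promoted`.
#' @export
run_joint_models <- function(data,
                             outcomes = c("dep_elevated", "anx_elevated"),
                             base_predictors = c("pa_intensity",
                                                 "na_intensity"),
                             promote = "na_instability",
                             alpha = 0.01,
                             covariates = c("age", "gender_female"),
                             conf_level = 0.99) {
  out <- list()
  for (oc in outcomes) {
    promoted <- promote
    if (identical(promote, "auto")) {
      indiv <- run_individual_models(
        data, indices = setdiff(index_names(), base_predictors),
        outcomes = oc, covariates = covariates, conf_level = conf_level)
      promoted <- indiv$table$index[indiv$table$p < alpha]
    }
    final_vars <- c(base_predictors, promoted)
    keep <- stats::complete.cases(data[c(oc, final_vars, covariates)])
    d <- data[keep, , drop = FALSE]
    initial <- fit_logistic(d, oc, base_predictors,
                            covariates = covariates,
                            conf_level = conf_level)
    final <- fit_logistic(d, oc, final_vars, covariates = covariates,
                          conf_level = conf_level)
    out[[oc]] <- list(
      initial = initial,
      final = final,
      comparison = lr_compare(initial, final),
      promoted = promoted
    )
  }
  out
}

#' Linear regression with standardized coefficients
#'
#' Ordinary least squares of a continuous subscale total on the same term
#' sets as the logistic models. Predictors enter standardized (as in
#' [fit_logistic()]); in addition a fully standardized beta
#' (`B * sd(x) / sd(y)`) is reported per term, which is invariant to
#' affine rescaling of both the term and the outcome.
#'
#' @inheritParams fit_logistic
#' @param outcome Name of the continuous outcome column.
#' @return An object of class `"linear_fit"`: `terms` (with `beta_std`),
#'   `n_used`, `rows`, `r_squared`, `adj_r_squared`, `sigma`.
#' @export
fit_linear <- function(data, outcome, predictors,
                       covariates = c("age", "gender_female"),
                       standardize_predictors = TRUE) {
  vars <- c(outcome, predictors, covariates)
  missing_cols <- setdiff(vars, names(data))
  if (length(missing_cols) > 0L)
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  rows <- which(stats::complete.cases(data[vars]))
  d <- data[rows, vars, drop = FALSE]
  if (standardize_predictors) {
    for (v in predictors) {
      s <- stats::sd(d[[v]])
      if (is.na(s) || s == 0) stop("zero variance in predictor ", v)
      d[[v]] <- (d[[v]] - mean(d[[v]])) / s
    }
  }
  fmla <- stats::reformulate(c(predictors, covariates), response = outcome)
  fit <- stats::lm(fmla, data = d)
  sm <- summary(fit)
  co <- sm$coefficients
  sy <- stats::sd(d[[outcome]])
  beta_std <- vapply(rownames(co), function(tm) {
    if (tm == "(Intercept)") return(NA_real_)
    co[tm, 1L] * stats::sd(d[[tm]]) / sy
  }, numeric(1))
  terms <- data.frame(
    term = rownames(co),
    b = co[, 1L], se = co[, 2L], beta_std = beta_std,
    t = co[, 3L], p = co[, 4L],
    row.names = NULL, stringsAsFactors = FALSE
  )
  ids <- if ("participant_id" %in% names(data))
    data$participant_id[rows] else rownames(data)[rows]
  structure(
    list(outcome = outcome, terms = terms, n_used = nrow(d), rows = ids,
         r_squared = sm$r.squared, adj_r_squared = sm$adj.r.squared,
         sigma = sm$sigma),
    class = "linear_fit"
  )
}

#' @export
print.linear_fit <- function(x, digits = 3, ...) {
  cat("Linear model for", x$outcome, " (n =", x$n_used, ")\n")
  tab <- x$terms
  tab[-1L] <- lapply(tab[-1L], round, digits)
  print(tab, row.names = FALSE)
  cat(sprintf("R2 = %.3f (adjusted %.3f)\n", x$r_squared, x$adj_r_squared))
  invisible(x)
}

#' Parallel linear models for the continuous subscale totals
#'
#' Mirrors [run_joint_models()] with ordinary least squares on the
#' continuous depression / anxiety totals: an initial model
#' `{PA intensity, NA intensity, age, gender}` and a final model adding
#' the promoted index, fitted on the final model's complete rows.
#'
#' @param data Joined profiles + outcomes.
#' @param outcomes Continuous outcome columns.
#' @inheritParams run_joint_models
#' @return A list per outcome with `initial` and `final`
#'   [fit_linear()] objects and the `promoted` set.
#' @export
run_linear_models <- function(data,
                              outcomes = c("dep_total", "anx_total"),
                              base_predictors = c("pa_intensity",
                                                  "na_intensity"),
                              promote = "na_instability",
                              covariates = c("age", "gender_female")) {
  out <- list()
  for (oc in outcomes) {
    final_vars <- c(base_predictors, promote)
    keep <- stats::complete.cases(data[c(oc, final_vars, covariates)])
    d <- data[keep, , drop = FALSE]
    out[[oc]] <- list(
      initial = fit_linear(d, oc, base_predictors, covariates = covariates),
      final = fit_linear(d, oc, final_vars, covariates = covariates),
      promoted = promote
    )
  }
  out
}
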
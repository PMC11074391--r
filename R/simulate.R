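## Synthetic EMA cohort generator: latent AR(1) affect per valence with
## item-level noise, round-then-clip emission to the 0..6 response scale,
## MCAR prompt missingness, and a symptom-outcome layer whose elevation
## probabilities follow a known logistic model on the person's realized
## affect dynamics. Every latent quantity is recorded as ground truth so
## downstream estimators can be tested for parameter recovery.

#' Simulate a stationary AR(1) series
#'
#' `x[t] = mu + phi * (x[t-1] - mu) + e[t]`, `e[t] ~ N(0, sigma^2)`,
#' initialized at the stationary distribution
#' `N(mu, sigma^2 / (1 - phi^2))`.
#'
#' @param n Series length.
#' @param mu Long-run mean.
#' @param phi Autoregressive coefficient, strictly inside (-1, 1).
#' @param sigma Innovation standard deviation (>= 0).
#' @return Numeric vector of length `n`.
#' @export
simulate_ar1 <- function(n, mu = 0, phi = 0.5, sigma = 1) {
  if (abs(phi) >= 1) stop("phi must be inside (-1, 1) for stationarity")
  stopifnot(sigma >= 0, n >= 1)
  x <- numeric(n)
  x[1L] <- stats::rnorm(1L, mu, if (sigma > 0) sigma / sqrt(1 - phi^2) else 0)
  if (n > 1L) {
    e <- stats::rnorm(n - 1L, 0, sigma)
    for (t in 2:n) x[t] <- mu + phi * (x[t - 1L] - mu) + e[t - 1L]
  }
  x
}

ar1_matrix <- function(n, len, mu, phi, sigma) {
  # one AR(1) series per row, vectorized over participants
  x <- matrix(0, n, len)
  x[, 1L] <- stats::rnorm(n, mu, ifelse(sigma > 0, sigma / sqrt(1 - phi^2), 0))
  for (t in seq_len(len)[-1L]) {
    x[, t] <- mu + phi * (x[, t - 1L] - mu) + stats::rnorm(n, 0, sigma)
  }
  x
}

clip_rating <- function(x) pmin(pmax(round(x), 0), 6)

distribute_total <- function(total, k, max_item = 4L) {
  # split a subscale total across k items, each bounded by max_item
  stopifnot(total >= 0, total <= k * max_item)
  if (total == 0) return(integer(k))
  alloc <- as.vector(stats::rmultinom(1L, total, rep(1, k)))
  while (any(alloc > max_item)) {
    over <- which(alloc > max_item)[1L]
    under <- which(alloc < max_item)
    j <- under[which.max(max_item - alloc[under])]
    alloc[over] <- alloc[over] - 1L
    alloc[j] <- alloc[j] + 1L
  }
  alloc
}

#' Configuration for the synthetic EMA cohort generator
#'
#' Person-level parameters are drawn from truncated normal distributions
#' (`list(mean, sd)`); autoregressive coefficients are clipped inside
#' (-1, 1). The symptom layer's logistic coefficients apply to raw age
#' (years), gender (female = 1) and the within-cohort z-scores of the
#' person's realized PA intensity, NA intensity and NA instability, so
#' they live on the same scale as the coefficients estimated by
#' [run_joint_models()]. Defaults emulate a 7x5-prompt protocol in a
#' middle-aged, mostly female general-population cohort with low average
#' NA (which produces the floor effects typical of NA items).
#'
#' @param n_participants Cohort size.
#' @param design An [ema_design()].
#' @param seed Integer seed; fixed seed gives byte-identical cohorts.
#' @param missing_rate Probability a scheduled prompt is unanswered
#'   (missing completely at random).
#' @param mu_pa,mu_na Latent mean affect distributions (0..6 scale).
#' @param phi_pa,phi_na Latent lag-1 autoregression distributions; draws
#'   are clipped to `+/- phi_bound`.
#' @param sigma_pa,sigma_na Innovation-scale distributions (floored at
#'   `sigma_floor`).
#' @param item_noise_sd Item-specific noise SD; larger values decouple
#'   same-valence items and so improve (lower) differentiation indices.
#' @param phi_bound,sigma_floor Truncation bounds for phi and sigma.
#' @param age Age distribution: `list(mean, sd, min, max)` in years.
#' @param prop_female Proportion of women.
#' @param dep_model,anx_model Named logistic coefficients
#'   (`intercept`, `age`, `gender_female`, `pa_intensity`,
#'   `na_intensity`, `na_instability`) for the elevated depression /
#'   anxiety outcome layers.
#' @param keep_complete Keep the complete (pre-missingness) prompt table
#'   in the returned cohort.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_participants = 221L,
                       design = ema_design(),
                       seed = 1L,
                       missing_rate = 0.2,
                       mu_pa = list(mean = 2.7, sd = 1.1),
                       mu_na = list(mean = 0.9, sd = 0.8),
                       phi_pa = list(mean = 0.35, sd = 0.15),
                       phi_na = list(mean = 0.30, sd = 0.15),
                       sigma_pa = list(mean = 0.75, sd = 0.25),
                       sigma_na = list(mean = 0.55, sd = 0.25),
                       item_noise_sd = 0.5,
                       phi_bound = 0.95,
                       sigma_floor = 0.05,
                       age = list(mean = 46, sd = 15, min = 18, max = 90),
                       prop_female = 0.73,
                       dep_model = c(intercept = 0.8, age = -0.05,
                                     gender_female = 0.4,
                                     pa_intensity = -0.6,
                                     na_intensity = 0.8,
                                     na_instability = 0.7),
                       anx_model = c(intercept = 0.3, age = -0.04,
                                     gender_female = 0.3,
                                     pa_intensity = -0.5,
                                     na_intensity = 0.9,
                                     na_instability = 0.7),
                       keep_complete = FALSE) {
  stopifnot(n_participants >= 1, missing_rate >= 0, missing_rate < 1,
            item_noise_sd >= 0, phi_bound > 0, phi_bound < 1)
  for (ph in list(phi_pa, phi_na)) {
    if (abs(ph$mean) >= 1)
      stop("phi distributions must be centred inside (-1, 1)")
  }
  coef_names <- c("intercept", "age", "gender_female", "pa_intensity",
                  "na_intensity", "na_instability")
  for (m in list(dep_model, anx_model)) {
    if (!all(coef_names %in% names(m)))
      stop("outcome models need coefficients: ",
           paste(coef_names, collapse = ", "))
  }
  structure(
    list(n_participants = as.integer(n_participants), design = design,
         seed = seed, missing_rate = missing_rate,
         mu_pa = mu_pa, mu_na = mu_na, phi_pa = phi_pa, phi_na = phi_na,
         sigma_pa = sigma_pa, sigma_na = sigma_na,
         item_noise_sd = item_noise_sd, phi_bound = phi_bound,
         sigma_floor = sigma_floor, age = age, prop_female = prop_female,
         dep_model = dep_model, anx_model = anx_model,
         keep_complete = keep_complete),
    class = "sim_config"
  )
}

draw_trunc <- function(n, spec, lo = -Inf, hi = Inf) {
  pmin(pmax(stats::rnorm(n, spec$mean, spec$sd), lo), hi)
}

slot_timestamp <- function(day, slot, prompts_per_day) {
  # prompts scheduled in windows between 9:00 and 21:00
  start_min <- 540 + (slot - 1) * (720 / prompts_per_day)
  minute <- start_min + stats::runif(length(day), 0, 60)
  sprintf("%sT%02d:%02d:00", as.Date("2021-05-09") + day,
          as.integer(minute %/% 60), as.integer(minute %% 60))
}

#' Simulate an EMA cohort with known ground truth
#'
#' For each participant and valence a latent affect series over the
#' scheduled prompts follows a stationary AR(1) process; each item rating
#' is the latent value plus item noise, rounded and clipped to 0..6.
#' "True" person-level indices are the indices [compute_profiles()] would
#' return on the complete (no-missingness) emitted data; the probability
#' of elevated depressive / anxiety symptoms follows the configured
#' logistic model on age, gender and the within-cohort z-scores of those
#' true indices, and subscale item vectors are generated consistent with
#' the drawn totals. Prompts are then dropped independently at the
#' configured missingness rate.
#'
#' @param config A [sim_config()].
#' @param seed Seed for all randomness (defaults to `config$seed`).
#' @return A list of class `"ema_cohort"`: `prompts` (post-missingness
#'   long records), `participants` (metadata with subscale items),
#'   `truth` (per-participant ground truth), and `complete_prompts` when
#'   `config$keep_complete` is set.
#' @export
simulate_cohort <- function(config = sim_config(), seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_participants
  des <- config$design
  len <- des$n_days * des$prompts_per_day
  ids <- sprintf("S%04d", seq_len(n))

  mu_pa <- draw_trunc(n, config$mu_pa, 0, 6)
  mu_na <- draw_trunc(n, config$mu_na, 0, 6)
  phi_pa <- draw_trunc(n, config$phi_pa, -config$phi_bound, config$phi_bound)
  phi_na <- draw_trunc(n, config$phi_na, -config$phi_bound, config$phi_bound)
  sigma_pa <- draw_trunc(n, config$sigma_pa, config$sigma_floor, Inf)
  sigma_na <- draw_trunc(n, config$sigma_na, config$sigma_floor, Inf)
  if (config$sigma_pa$sd == 0 && config$sigma_pa$mean == 0) sigma_pa[] <- 0
  if (config$sigma_na$sd == 0 && config$sigma_na$mean == 0) sigma_na[] <- 0
  age <- round(draw_trunc(n, config$age, config$age$min, config$age$max))
  gender_female <- stats::rbinom(n, 1L, config$prop_female)

  x_pa <- ar1_matrix(n, len, mu_pa, phi_pa, sigma_pa)
  x_na <- ar1_matrix(n, len, mu_na, phi_na, sigma_na)
  mu_tired <- draw_trunc(n, list(mean = 2.5, sd = 1.0), 0, 6)

  emit <- function(latent_vec, n_obs) {
    clip_rating(latent_vec + stats::rnorm(n_obs, 0, config$item_noise_sd))
  }
  n_obs <- n * len
  day <- rep(rep(seq_len(des$n_days), each = des$prompts_per_day), times = n)
  slot <- rep(rep(seq_len(des$prompts_per_day), times = des$n_days),
              times = n)
  pa_flat <- as.vector(t(x_pa))
  na_flat <- as.vector(t(x_na))
  complete <- data.frame(
    participant_id = rep(ids, each = len),
    day = day,
    slot = slot,
    timestamp = slot_timestamp(day, slot, des$prompts_per_day),
    stringsAsFactors = FALSE
  )
  for (item in des$pa_items) complete[[item]] <- emit(pa_flat, n_obs)
  for (item in des$na_items) complete[[item]] <- emit(na_flat, n_obs)
  extra <- setdiff(des$items, c(des$pa_items, des$na_items))
  for (item in extra)
    complete[[item]] <- clip_rating(rep(mu_tired, each = len) +
                                      stats::rnorm(n_obs, 0, 1))

  # realized true indices on the complete emitted data
  truth_prof <- compute_profiles(complete, des)
  truth_prof <- truth_prof[match(ids, truth_prof$participant_id), ]
  zs <- function(v) {
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0) return(rep(0, length(v)))
    (v - mean(v)) / s
  }
  z_pa <- zs(truth_prof$pa_intensity)
  z_na <- zs(truth_prof$na_intensity)
  z_in <- zs(truth_prof$na_instability)

  linpred <- function(beta) {
    beta[["intercept"]] + beta[["age"]] * age +
      beta[["gender_female"]] * gender_female +
      beta[["pa_intensity"]] * z_pa + beta[["na_intensity"]] * z_na +
      beta[["na_instability"]] * z_in
  }
  lp_dep <- linpred(config$dep_model)
  lp_anx <- linpred(config$anx_model)
  p_dep <- stats::plogis(lp_dep)
  p_anx <- stats::plogis(lp_anx)
  dep_elev <- stats::rbinom(n, 1L, p_dep)
  anx_elev <- stats::rbinom(n, 1L, p_anx)

  draw_total <- function(elev, p, n_items) {
    cutoff <- 11L
    hi_max <- 4L * n_items - (cutoff + 1L)
    ifelse(elev == 1L,
           cutoff + 1L + stats::rbinom(n, hi_max, 0.15 + 0.5 * p),
           stats::rbinom(n, cutoff, 0.15 + 0.55 * p))
  }
  dep_total <- draw_total(dep_elev, p_dep, 8L)
  anx_total <- draw_total(anx_elev, p_anx, 6L)

  dep_items <- t(vapply(dep_total, distribute_total, integer(8L), k = 8L))
  anx_items <- t(vapply(anx_total, distribute_total, integer(6L), k = 6L))
  participants <- data.frame(
    participant_id = ids,
    age = age,
    gender = ifelse(gender_female == 1L, "f", "m"),
    stringsAsFactors = FALSE
  )
  participants[paste0("dep_", 1:8)] <- dep_items
  participants[paste0("anx_", 1:6)] <- anx_items

  answered <- stats::runif(n_obs) >= config$missing_rate
  prompts <- complete[answered, , drop = FALSE]
  rownames(prompts) <- NULL

  truth <- data.frame(
    participant_id = ids, age = age, gender_female = gender_female,
    mu_pa = mu_pa, mu_na = mu_na, phi_pa = phi_pa, phi_na = phi_na,
    sigma_pa = sigma_pa, sigma_na = sigma_na,
    stringsAsFactors = FALSE
  )
  for (v in c("pa_intensity", "na_intensity", "pa_instability",
              "na_instability", "pa_inertia_z", "na_inertia_z",
              "pa_diff_z", "na_diff_z"))
    truth[[paste0("true_", v)]] <- truth_prof[[v]]
  truth$z_pa_intensity <- z_pa
  truth$z_na_intensity <- z_na
  truth$z_na_instability <- z_in
  truth$lp_dep <- lp_dep
  truth$p_dep <- p_dep
  truth$lp_anx <- lp_anx
  truth$p_anx <- p_anx
  truth$dep_elevated <- dep_elev
  truth$anx_elevated <- anx_elev
  truth$dep_total <- dep_total
  truth$anx_total <- anx_total

  out <- list(prompts = prompts, participants = participants, truth = truth,
              config = config)
  if (isTRUE(config$keep_complete)) out$complete_prompts <- complete
  structure(out, class = "ema_cohort")
}

#' @export
print.ema_cohort <- function(x, ...) {
  cat("Synthetic EMA cohort:", nrow(x$truth), "participants,",
      nrow(x$prompts), "answered prompts\n")
  invisible(x)
}

#' Summarize the spread of the generator's ground-truth parameters
#'
#' Descriptive summary (mean, SD, min, max) of every numeric ground-truth
#' column; used in parameter-recovery diagnostics.
#'
#' @param truth The `truth` component of an [simulate_cohort()] result.
#' @return A data frame with one row per numeric ground-truth variable;
#'   empty for an empty cohort.
#' @export
sample_size_report <- function(truth) {
  num <- names(truth)[vapply(truth, is.numeric, logical(1))]
  if (nrow(truth) == 0L || length(num) == 0L) {
    return(data.frame(variable = character(0), mean = numeric(0),
                      sd = numeric(0), min = numeric(0), max = numeric(0)))
  }
  do.call(rbind, lapply(num, function(v) {
    x <- truth[[v]]
    data.frame(variable = v, mean = mean(x, na.rm = TRUE),
               sd = stats::sd(x), min = suppressWarnings(min(x, na.rm = TRUE)),
               max = suppressWarnings(max(x, na.rm = TRUE)),
               stringsAsFactors = FALSE)
  }))
}
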
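test_that("standardize centres, scales, and is affine invariant", {
  expect_equal(standardize(c(1, 2, 3)), c(-1, 0, 1))
  set.seed(501)
  x <- rnorm(40)
  z <- standardize(x)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  expect_equal(standardize(z), z, tolerance = 1e-12)
  expect_equal(standardize(3.2 * x + 7), z, tolerance = 1e-10)
  expect_error(standardize(rep(2, 10)), "zero variance")
  expect_error(standardize(c(1, NA, NA)), ">= 2 non-missing")
  # missing values preserved, ignored in the moments
  xm <- c(x, NA)
  expect_true(is.na(standardize(xm)[41L]))
})

test_that("welch_t matches stats::t.test and its formula properties", {
  set.seed(502)
  for (i in 1:20) {
    g1 <- rnorm(sample(10:60, 1L), mean = rnorm(1), sd = runif(1, 0.5, 2))
    g2 <- rnorm(sample(10:60, 1L), mean = rnorm(1), sd = runif(1, 0.5, 2))
    w <- welch_t(mean(g1), sd(g1), length(g1), mean(g2), sd(g2), length(g2))
    tt <- t.test(g1, g2)
    expect_equal(w$t, unname(tt$statistic), tolerance = 1e-10)
    expect_equal(w$df, unname(tt$parameter), tolerance = 1e-10)
    expect_equal(w$p, tt$p.value, tolerance = 1e-10)
  }
  expect_equal(welch_t(1.3, 1, 20, 1.3, 2, 25)$t, 0)
  w1 <- welch_t(0, 1, 20, 1, 1, 30)
  w2 <- welch_t(0, 1, 40, 1, 1, 60)
  expect_equal(w2$t / w1$t, sqrt(2), tolerance = 1e-12)
  expect_error(welch_t(0, 0, 10, 1, 0, 10), "undefined")
})

test_that("odds-ratio intervals are symmetric on the log scale", {
  out <- or_ci99(0, 0.5)
  expect_equal(out$or, 1)
  expect_equal(out$lo * out$hi, 1, tolerance = 1e-12)
  expect_equal(log(out$hi / out$or), log(out$or / out$lo), tolerance = 1e-12)
  expect_equal(or_ci99(0.7, 0.2)$or, exp(0.7))
  expect_error(or_ci99(1, 0))
})

test_that("logistic fits agree with direct likelihood maximization", {
  set.seed(503)
  for (i in 1:10) {
    n <- 120L
    d <- data.frame(x1 = rnorm(n), x2 = rnorm(n),
                    age = round(runif(n, 20, 70)),
                    gender_female = rbinom(n, 1L, 0.6))
    lp <- 0.3 + 0.8 * d$x1 - 0.5 * d$x2 - 0.01 * d$age +
      0.3 * d$gender_female
    d$y <- rbinom(n, 1L, plogis(lp))
    f <- fit_logistic(d, "y", c("x1", "x2"),
                      standardize_predictors = FALSE)
    X <- cbind(1, d$x1, d$x2, d$age, d$gender_female)
    expect_equal(f$terms$b, oracle_logistic(X, d$y), tolerance = 1e-6)
    expect_equal(f$aic, 2 * f$k - 2 * f$ll, tolerance = 1e-10)
    expect_true(all(f$terms$ci_lo < f$terms$or & f$terms$or < f$terms$ci_hi))
  }
})

test_that("ORs for standardized predictors are invariant to the raw scale", {
  set.seed(504)
  n <- 250L
  d <- data.frame(ix = rnorm(n, 2, 0.7), age = round(runif(n, 20, 70)),
                  gender_female = rbinom(n, 1L, 0.6))
  d$y <- rbinom(n, 1L, plogis(-0.5 + 0.9 * standardize(d$ix)))
  f1 <- fit_logistic(d, "y", "ix")
  d2 <- d
  d2$ix <- 100 * d$ix - 42
  f2 <- fit_logistic(d2, "y", "ix")
  expect_equal(f1$terms$or, f2$terms$or, tolerance = 1e-9)
})

test_that("null and degenerate logistic cases behave as specified", {
  set.seed(505)
  d <- data.frame(y = rep(c(0L, 1L), each = 30L), age = rnorm(60, 40, 10))
  # intercept-only model on a balanced outcome: intercept 0, OR 1
  f <- fit_logistic(d, "y", character(0), covariates = character(0))
  expect_equal(f$terms$b, 0, tolerance = 1e-9)
  expect_equal(f$terms$or, 1, tolerance = 1e-9)
  expect_equal(pseudo_r2_adjusted(f), 0, tolerance = 1e-12)
  d$y <- 1L
  expect_error(fit_logistic(d, "y", character(0), covariates = "age"),
               "single class")
})

test_that("nested model comparison is internally consistent", {
  set.seed(506)
  n <- 200L
  d <- data.frame(x1 = rnorm(n), x2 = rnorm(n),
                  age = round(runif(n, 20, 70)),
                  gender_female = rbinom(n, 1L, 0.5))
  d$y <- rbinom(n, 1L, plogis(0.6 * d$x1))
  initial <- fit_logistic(d, "y", "x1")
  final <- fit_logistic(d, "y", c("x1", "x2"))
  cmp <- lr_compare(initial, final)
  expect_equal(cmp$chi2, 2 * (final$ll - initial$ll), tolerance = 1e-10)
  expect_equal(cmp$df, 1L)
  expect_equal(cmp$delta_aic, 2 * cmp$df - cmp$chi2, tolerance = 1e-10)
  expect_gte(cmp$chi2, 0)

  self <- lr_compare(final, final)
  expect_equal(self$chi2, 0, tolerance = 1e-10)
  expect_equal(self$df, 0L)

  other <- fit_logistic(d[1:150, ], "y", c("x1", "x2"))
  expect_error(lr_compare(initial, other), "different rows")
})

test_that("adding noise predictors lowers the adjusted pseudo-R2 on average", {
  set.seed(507)
  diffs <- replicate(60, {
    n <- 150L
    d <- data.frame(x1 = rnorm(n), noise = rnorm(n),
                    age = round(runif(n, 20, 70)),
                    gender_female = rbinom(n, 1L, 0.5))
    d$y <- rbinom(n, 1L, plogis(0.7 * d$x1))
    base <- fit_logistic(d, "y", "x1")
    more <- fit_logistic(d, "y", c("x1", "noise"))
    more$pseudo_r2_adjusted - base$pseudo_r2_adjusted
  })
  expect_lt(mean(diffs), 0)
})

test_that("linear fits recover exact relations and scale-free betas", {
  set.seed(508)
  n <- 120L
  d <- data.frame(x1 = rnorm(n), x2 = rnorm(n),
                  age = round(runif(n, 20, 70)),
                  gender_female = rbinom(n, 1L, 0.5))
  d$y <- 2 + 1.5 * d$x1 - 0.8 * d$x2 + 0.1 * d$age
  f <- suppressWarnings(fit_linear(d, "y", c("x1", "x2")))
  expect_equal(f$r_squared, 1, tolerance = 1e-12)
  expect_lt(f$sigma, 1e-10)

  d$y <- d$y + rnorm(n)
  f1 <- fit_linear(d, "y", c("x1", "x2"), standardize_predictors = FALSE)
  d2 <- d
  d2$x1 <- 10 * d$x1 + 5
  f2 <- fit_linear(d2, "y", c("x1", "x2"), standardize_predictors = FALSE)
  b1 <- f1$terms$beta_std[f1$terms$term == "x1"]
  b2 <- f2$terms$beta_std[f2$terms$term == "x1"]
  expect_equal(b1, b2, tolerance = 1e-10)
})

test_that("model runners produce the expected table shapes and term sets", {
  co <- simulate_cohort(sim_config(n_participants = 250L, seed = 42L))
  dat <- merge(compute_profiles(co$prompts),
               score_participants(co$participants), by = "participant_id")
  indiv <- run_individual_models(dat)
  expect_equal(nrow(indiv$table), 16L)
  expect_setequal(unique(indiv$table$outcome),
                  c("dep_elevated", "anx_elevated"))

  joint <- run_joint_models(dat)
  for (oc in names(joint)) {
    expect_setequal(joint[[oc]]$final$terms$term,
                    union(joint[[oc]]$initial$terms$term, "na_instability"))
    expect_equal(joint[[oc]]$initial$n_used, joint[[oc]]$final$n_used)
  }

  lin <- run_linear_models(dat)
  expect_named(lin, c("dep_total", "anx_total"))
  expect_true(all(c("na_instability") %in% lin$dep_total$final$terms$term))
})
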
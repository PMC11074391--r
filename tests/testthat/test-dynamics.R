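test_that("rmssd matches the closed form and handles short/missing series", {
  expect_equal(rmssd(c(2, 2, 2)), 0)
  expect_equal(rmssd(c(0, 2, 1, 3)), sqrt(3))
  expect_true(is.na(rmssd(5)))
  expect_true(is.na(rmssd(c(NA, 4, NA))))
  # skipped middle slot: successive answered prompts by default,
  # adjacent scheduled slots under the strict option
  expect_equal(rmssd(c(1, NA, 3)), 2)
  expect_true(is.na(rmssd(c(1, NA, 3), strict_adjacent = TRUE)))
  expect_equal(rmssd(c(1, 2, NA, 4), strict_adjacent = TRUE), 1)
})

test_that("rmssd is shift invariant and absolutely homogeneous", {
  set.seed(301)
  for (i in 1:50) {
    x <- rnorm(sample(2:8, 1L))
    c0 <- rnorm(1)
    a <- rnorm(1)
    expect_equal(rmssd(x + c0), rmssd(x))
    expect_equal(rmssd(a * x), abs(a) * rmssd(x))
    expect_equal(rmssd(x), oracle_rmssd(x))
  }
})

test_that("lag-1 autocorrelation respects day breaks", {
  expect_equal(lag1_autocor(1:5, day = rep(1L, 5L)), 1)
  expect_equal(lag1_autocor(c(0, 1, 0, 1), day = rep(1L, 4L)), -1)
  # the cross-day (3,10) pair is excluded
  x <- c(1, 2, 3, 10, 11, 12)
  d <- rep(1:2, each = 3L)
  expect_equal(lag1_autocor(x, d), oracle_lag1(x, d))
  # and differs from the estimate that ignores day boundaries
  expect_false(isTRUE(all.equal(lag1_autocor(x, d),
                                cor(x[-6], x[-1]))))
  # minimum pairs and zero variance yield missing
  expect_true(is.na(lag1_autocor(c(1, 2, 3), day = c(1L, 1L, 2L))))
  expect_true(is.na(lag1_autocor(rep(2, 6), day = rep(1L, 6L))))
})

test_that("on gap-free single days the estimator is the textbook lag-1 Pearson", {
  set.seed(302)
  for (i in 1:200) {
    n <- sample(4:35, 1L)
    x <- rnorm(n)
    r <- lag1_autocor(x, day = rep(1L, n))
    expect_equal(r, cor(x[-n], x[-1]), tolerance = 1e-12)
    expect_true(abs(r) <= 1 + 1e-12)
    # invariance under positive affine transforms
    expect_equal(lag1_autocor(2.5 * x + 3, day = rep(1L, n)), r,
                 tolerance = 1e-9)
  }
})

test_that("fisher_z is odd, increasing, clamped, and invertible", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), atanh(0.5))
  expect_equal(round(fisher_z(0.5), 4), 0.5493)
  expect_equal(fisher_z(-0.5), -fisher_z(0.5))
  expect_equal(fisher_z(1), atanh(1 - 1e-7))
  expect_equal(fisher_z(-1.5), -atanh(1 - 1e-7))
  r <- seq(-0.95, 0.95, by = 0.05)
  expect_true(all(diff(fisher_z(r)) > 0))
  expect_equal(tanh(fisher_z(r)), r, tolerance = 1e-9)
})

test_that("differentiation indices summarize pairwise item coupling", {
  set.seed(303)
  x <- rnorm(30)
  # perfectly coupled items hit the clamp
  expect_equal(na_differentiation(cbind(x, x, x, x)), atanh(1 - 1e-7))
  expect_equal(pa_differentiation(x, x), atanh(1 - 1e-7))
  # zero-variance series yield missing
  expect_true(is.na(pa_differentiation(rep(1, 10), rnorm(10))))
  # independent long series give near-zero mean z
  m <- matrix(rnorm(4e4), ncol = 4L)
  expect_lt(abs(na_differentiation(m)), 0.05)
  # random fixtures match the brute-force oracle
  for (i in 1:100) {
    m <- matrix(rnorm(4 * sample(5:20, 1L)), ncol = 4L)
    if (runif(1) < 0.2) m[, 1L] <- m[, 2L] + rnorm(nrow(m), sd = 0.1)
    expect_equal(na_differentiation(m), oracle_pairwise_z(m))
    expect_equal(pa_differentiation(m[, 1L], m[, 2L]),
                 oracle_pairwise_z(m[, 1:2]))
  }
})

test_that("intensity and instability average day-level values, not prompts", {
  rec <- rbind(
    mean_prompts("p", 1L, 1L, pa = 0, na = 1),
    mean_prompts("p", 1L, 2L, pa = 2, na = 1),
    mean_prompts("p", 2L, 1L, pa = 4, na = 3),
    mean_prompts("p", 2L, 2L, pa = 4, na = 3),
    mean_prompts("p", 2L, 3L, pa = 4, na = 3),
    mean_prompts("p", 3L, 1L, pa = 1, na = 0),
    mean_prompts("p", 3L, 2L, pa = 3, na = 2)
  )
  prof <- compute_profiles(rec)
  # day means 1, 4, 2 -> 7/3; the grand prompt mean would be 18/7
  expect_equal(prof$pa_intensity, 7 / 3)
  expect_false(isTRUE(all.equal(prof$pa_intensity, 18 / 7)))
  # daily RMSSDs: 2, 0, 2 -> mean 4/3
  expect_equal(prof$pa_instability, 4 / 3)
  expect_equal(prof$n_prompts, 7L)
  expect_equal(prof$n_days, 3L)
})

test_that("vectorized profiles equal the per-person index functions", {
  set.seed(304)
  for (rep in 1:15) {
    rec <- do.call(rbind, lapply(1:5, function(i) {
      make_prompts(sprintf("q%d", i),
                   sample(2:5, sample(3:7, 1L), replace = TRUE))
    }))
    prof <- compute_profiles(rec)
    rec <- prompt_affect_means(rec)
    for (id in unique(rec$participant_id)) {
      sub <- rec[rec$participant_id == id, ]
      sub <- sub[order(sub$day, sub$slot), ]
      row <- prof[prof$participant_id == id, ]
      day_means <- tapply(sub$pa_mean, sub$day, mean)
      expect_equal(row$pa_intensity, mean(day_means))
      daily <- tapply(sub$na_mean, sub$day, rmssd)
      expect_equal(row$na_instability, mean(daily[!is.na(daily)]))
      expect_equal(row$na_inertia_z,
                   fisher_z(lag1_autocor(sub$na_mean, sub$day)))
      expect_equal(row$pa_diff_z,
                   pa_differentiation(sub$joy_excitement,
                                      sub$satisfaction_relaxation))
      expect_equal(row$na_diff_z,
                   na_differentiation(as.matrix(sub[ema_items[3:6]])))
    }
  }
})

test_that("degenerate zero-noise cohorts give flat profiles", {
  cfg <- sim_config(n_participants = 3L, seed = 9L, missing_rate = 0,
                    mu_pa = list(mean = 3.4, sd = 0),
                    mu_na = list(mean = 1.2, sd = 0),
                    sigma_pa = list(mean = 0, sd = 0),
                    sigma_na = list(mean = 0, sd = 0),
                    item_noise_sd = 0)
  co <- simulate_cohort(cfg)
  prof <- compute_profiles(co$prompts)
  expect_equal(prof$pa_intensity, rep(3, 3L))   # clip(round(3.4)) = 3
  expect_equal(prof$na_intensity, rep(1, 3L))
  expect_equal(prof$pa_instability, rep(0, 3L))
  expect_true(all(is.na(prof$pa_inertia_z)))
  expect_true(all(is.na(prof$na_diff_z)))
})
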
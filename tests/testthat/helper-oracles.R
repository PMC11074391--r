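# Independent brute-force oracles, written only from the index and
# likelihood definitions; they deliberately share no code with the
# package implementations they check.

oracle_rmssd <- function(x) {
  v <- x[!is.na(x)]
  if (length(v) < 2L) return(NA_real_)
  d <- v[-1L] - v[-length(v)]
  sqrt(sum(d^2) / length(d))
}

oracle_lag1 <- function(x, day, min_pairs = 3L) {
  lead <- c()
  lag <- c()
  for (t in seq_len(length(x) - 1L)) {
    if (day[t] == day[t + 1L]) {
      lead <- c(lead, x[t])
      lag <- c(lag, x[t + 1L])
    }
  }
  if (length(lead) < min_pairs) return(NA_real_)
  if (length(unique(lead)) == 1L || length(unique(lag)) == 1L)
    return(NA_real_)
  mx <- mean(lead); my <- mean(lag)
  num <- sum((lead - mx) * (lag - my))
  den <- sqrt(sum((lead - mx)^2) * sum((lag - my)^2))
  if (den == 0) return(NA_real_)
  num / den
}

oracle_pairwise_z <- function(mat, min_obs = 3L) {
  k <- ncol(mat)
  zs <- c()
  for (i in seq_len(k - 1L)) {
    for (j in seq.int(i + 1L, k)) {
      xi <- mat[, i]; xj <- mat[, j]
      ok <- !is.na(xi) & !is.na(xj)
      xi <- xi[ok]; xj <- xj[ok]
      if (length(xi) < min_obs) next
      if (length(unique(xi)) == 1L || length(unique(xj)) == 1L) next
      mx <- mean(xi); my <- mean(xj)
      r <- sum((xi - mx) * (xj - my)) /
        sqrt(sum((xi - mx)^2) * sum((xj - my)^2))
      r <- min(max(r, -(1 - 1e-7)), 1 - 1e-7)
      zs <- c(zs, 0.5 * log((1 + r) / (1 - r)))
    }
  }
  if (length(zs) == 0L) NA_real_ else mean(zs)
}

# direct likelihood maximization by Newton iteration on the Bernoulli
# log-likelihood (no glm machinery)
oracle_logistic <- function(X, y, max_iter = 50L, tol = 1e-12) {
  b <- rep(0, ncol(X))
  for (it in seq_len(max_iter)) {
    eta <- as.vector(X %*% b)
    p <- 1 / (1 + exp(-eta))
    g <- as.vector(t(X) %*% (y - p))
    H <- t(X) %*% (X * (p * (1 - p)))
    step <- solve(H, g)
    b <- b + step
    if (max(abs(step)) < tol) break
  }
  b
}

# prompt-record builder: one participant, day-pattern given as a vector of
# prompts per day; ratings drawn 0..6 (caller controls the RNG state)
make_prompts <- function(id, day_counts, items = ema_items) {
  rows <- list()
  for (d in seq_along(day_counts)) {
    nslots <- day_counts[d]
    if (nslots == 0L) next
    for (s in seq_len(nslots)) {
      rec <- data.frame(participant_id = id, day = d, slot = s,
                        timestamp = NA_character_,
                        stringsAsFactors = FALSE)
      for (item in items) rec[[item]] <- sample(0:6, 1L)
      rows[[length(rows) + 1L]] <- rec
    }
  }
  do.call(rbind, rows)
}

make_cohort_prompts <- function(n, day_counts = rep(5L, 7L)) {
  do.call(rbind, lapply(seq_len(n), function(i) {
    make_prompts(sprintf("T%03d", i), day_counts)
  }))
}

# constant-rating prompt rows with specified PA / NA prompt-level means
# (both PA items set to pa, all four NA items set to na)
mean_prompts <- function(id, day, slot, pa, na) {
  rec <- data.frame(participant_id = id, day = day, slot = slot,
                    timestamp = NA_character_, stringsAsFactors = FALSE)
  for (item in ema_items[1:2]) rec[[item]] <- pa
  for (item in ema_items[3:6]) rec[[item]] <- na
  rec[[ema_items[7]]] <- 0L
  rec
}
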
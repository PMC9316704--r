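# Builders for small crafted corpora used across the module tests.

blank_trials <- function(n) {
  data.frame(
    review_id = rep("R1", n), trial_id = sprintf("T%02d", seq_len(n)),
    pub_year = rep(2000L, n), outcome_kind = rep("continuous", n),
    direction = rep("benefit", n), declared_measure = rep("MD", n),
    active_n = rep(50L, n), placebo_n = rep(50L, n),
    active_mean = rep(NA_real_, n), active_sd = rep(NA_real_, n),
    placebo_mean = rep(NA_real_, n), placebo_sd = rep(NA_real_, n),
    active_events = rep(NA_real_, n), placebo_events = rep(NA_real_, n),
    stringsAsFactors = FALSE
  )
}

# continuous review: one row per (year, active_mean); placebo mean 0, sds 1
make_cont_review <- function(years, active_means, review_id = "R1",
                             direction = "benefit", n = 50L) {
  k <- length(years)
  tr <- blank_trials(k)
  tr$review_id <- rep(review_id, k)
  tr$trial_id <- sprintf("%s_T%02d", review_id, seq_len(k))
  tr$pub_year <- as.integer(years)
  tr$direction <- rep(direction, k)
  tr$active_n <- tr$placebo_n <- rep(as.integer(n), k)
  tr$active_mean <- active_means
  tr$placebo_mean <- rep(0, k)
  tr$active_sd <- tr$placebo_sd <- rep(1, k)
  tr
}

make_bin_review <- function(years, active_events, placebo_events,
                            review_id = "R1", direction = "benefit",
                            n = 100L) {
  k <- length(years)
  tr <- blank_trials(k)
  tr$review_id <- rep(review_id, k)
  tr$trial_id <- sprintf("%s_T%02d", review_id, seq_len(k))
  tr$pub_year <- as.integer(years)
  tr$outcome_kind <- rep("binary", k)
  tr$declared_measure <- rep("RR", k)
  tr$direction <- rep(direction, k)
  tr$active_n <- tr$placebo_n <- rep(as.integer(n), k)
  tr$active_events <- active_events
  tr$placebo_events <- placebo_events
  tr
}

# random effect estimates for pooling property tests
random_effects <- function(k) {
  constancer:::new_effect(stats::rnorm(k, 0.3, 0.4),
                          stats::runif(k, 0.01, 0.2),
                          sample(50:500, k, replace = TRUE))
}

# independent brute-force pooling oracle, coded from the formulas
oracle_pool <- function(y, v, method) {
  w <- 1 / v
  mu_f <- sum(w * y) / sum(w)
  q <- sum(w * (y - mu_f)^2)
  df <- length(y) - 1
  tau2 <- 0
  if (df > 0) {
    c_dl <- sum(w) - sum(w^2) / sum(w)
    tau2 <- max(0, (q - df) / c_dl)
  }
  if (method == "fixed") {
    list(smd = mu_f, se = sqrt(1 / sum(w)), tau2 = tau2)
  } else {
    ws <- 1 / (v + tau2)
    list(smd = sum(ws * y) / sum(ws), se = sqrt(1 / sum(ws)), tau2 = tau2)
  }
}

coef_est <- function(fit, term) {
  fit$coefficients$estimate[match(term, fit$coefficients$term)]
}

# independent weighted normal-equation solver
oracle_wls <- function(y, X, w) {
  XtW <- t(X * w)
  beta <- solve(XtW %*% X, XtW %*% y)
  res <- y - X %*% beta
  df <- length(y) - ncol(X)
  sigma2 <- sum(w * res^2) / df
  list(beta = drop(beta), vcov = sigma2 * solve(XtW %*% X), sigma2 = sigma2)
}
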
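make_rows <- function(n, beta = c(intercept = 0.2, smd_dl = 0.9),
                      noise_sd = 0.1, seed = 1) {
  simulate_regression_rows(beta, n_rows = n, noise_sd = noise_sd,
                           seed = seed)$rows
}

test_that("noiseless rows are fitted exactly", {
  rows <- make_rows(50, noise_sd = 0)
  fit <- fit_wls(rows, "smd_dl")
  expect_equal(coef_est(fit, "(Intercept)"), 0.2, tolerance = 1e-8)
  expect_equal(coef_est(fit, "smd_dl"), 0.9, tolerance = 1e-8)
  expect_equal(fit$adj_r2, 1, tolerance = 1e-8)
})

test_that("equal weights reproduce the unweighted normal-equation oracle", {
  rows <- make_rows(40, noise_sd = 0.3, seed = 3)
  rows$weight <- 1
  fit <- fit_wls(rows, c("smd_dl", "year_diff", "year_last"))
  X <- cbind(1, rows$smd_dl, rows$year_diff, rows$year_last)
  o <- oracle_wls(rows$smd_lt, X, rep(1, nrow(rows)))
  expect_equal(fit$coefficients$estimate, unname(o$beta), tolerance = 1e-8)
  expect_equal(fit$coefficients$se, unname(sqrt(diag(o$vcov))),
               tolerance = 1e-8)
})

test_that("WLS matches the weighted normal-equation oracle on random instances", {
  set.seed(99)
  for (i in 1:50) {
    n <- 30
    p <- sample(1:3, 1)
    covs <- c("smd_dl", "year_diff", "year_last")[seq_len(p)]
    rows <- make_rows(n, noise_sd = 0.4, seed = i)
    fit <- fit_wls(rows, covs)
    X <- as.matrix(cbind(1, rows[covs]))
    o <- oracle_wls(rows$smd_lt, X, rows$weight)
    expect_equal(fit$coefficients$estimate, unname(o$beta), tolerance = 1e-8)
    expect_equal(fit$coefficients$se, unname(sqrt(diag(o$vcov))),
                 tolerance = 1e-8)
    expect_equal(fit$residual_variance, o$sigma2, tolerance = 1e-8)
  }
})

test_that("coefficients and summaries are invariant to weight rescaling", {
  rows <- make_rows(60, noise_sd = 0.2, seed = 8)
  f1 <- fit_wls(rows, c("smd_dl", "year_last"))
  rows$weight <- rows$weight * 1234.5
  f2 <- fit_wls(rows, c("smd_dl", "year_last"))
  expect_equal(f1$coefficients$estimate, f2$coefficients$estimate,
               tolerance = 1e-10)
  expect_equal(f1$coefficients$se, f2$coefficients$se, tolerance = 1e-10)
  expect_equal(f1$adj_r2, f2$adj_r2, tolerance = 1e-10)
})

test_that("two points and one covariate give a saturated, exact fit", {
  rows <- data.frame(review_id = c("a", "b"), smd_lt = c(0.1, 0.7),
                     smd_dl = c(0.2, 0.6), year_diff = c(1, 2),
                     year_last = c(2000, 2001), weight = c(100, 300))
  fit <- fit_wls(rows, "smd_dl")
  pred <- fit$coefficients$estimate[1] + fit$coefficients$estimate[2] * rows$smd_dl
  expect_equal(pred, rows$smd_lt, tolerance = 1e-10)
})

test_that("degenerate designs and weights are rejected with names", {
  rows <- make_rows(30)
  rows$year_last <- rows$year_diff      # exact collinearity
  expect_error(fit_wls(rows, c("smd_dl", "year_diff", "year_last")),
               "year_last")
  rows2 <- make_rows(30)
  rows2$weight[3] <- 0
  expect_error(fit_wls(rows2, "smd_dl"), "weights must be positive")
  expect_error(fit_wls(make_rows(30)[1:2, ], c("smd_dl", "year_diff")),
               "at least")
})

test_that("centering the year changes only the intercept", {
  rows <- make_rows(80, beta = c(intercept = 36, smd_dl = 0.9,
                                 year_last = -0.018),
                    noise_sd = 0.2, seed = 12)
  f_raw <- fit_wls(rows, c("smd_dl", "year_last"))
  f_c <- fit_wls(rows, c("smd_dl", "year_last"), center_year = TRUE)
  expect_equal(coef_est(f_raw, "smd_dl"), coef_est(f_c, "smd_dl"),
               tolerance = 1e-10)
  expect_equal(coef_est(f_raw, "year_last"), coef_est(f_c, "year_last"),
               tolerance = 1e-10)
  expect_false(isTRUE(all.equal(coef_est(f_raw, "(Intercept)"),
                                coef_est(f_c, "(Intercept)"))))
})

test_that("stepwise keeps a strong covariate and usually drops a null one", {
  kept_strong <- 0L
  dropped_null <- 0L
  for (i in 1:100) {
    rows <- simulate_regression_rows(
      c(intercept = 36.14, smd_dl = 0.88, year_last = -0.018),
      n_rows = 500, noise_sd = 0.2, seed = 1000 + i
    )$rows
    fit <- stepwise_select(rows)
    if ("year_last" %in% fit$selected) kept_strong <- kept_strong + 1L
    if (!("year_diff" %in% fit$selected)) dropped_null <- dropped_null + 1L
  }
  expect_equal(kept_strong, 100L)
  expect_gte(dropped_null, 90L)
})

test_that("stepwise with no candidates returns the core model", {
  rows <- make_rows(50, noise_sd = 0.2, seed = 2)
  fit <- stepwise_select(rows, candidates = character(0))
  expect_equal(fit$selected, "smd_dl")
  expect_equal(fit$coefficients$term, c("(Intercept)", "smd_dl"))
  expect_error(stepwise_select(rows, enter = 0.2, remove = 0.1), "thresholds")
})

test_that("prediction is the linear combination of the printed coefficients", {
  # fix coefficients to the published point estimates and evaluate by hand
  fit <- structure(list(
    coefficients = data.frame(
      term = c("(Intercept)", "smd_dl", "year_diff", "year_last"),
      estimate = c(36.14, 0.88, -0.009, -0.018),
      se = NA, ci_low = NA, ci_high = NA, p_value = NA
    ),
    selected = c("smd_dl", "year_diff", "year_last"),
    residual_variance = 0.04, median_weight = 1160,
    vcov = matrix(0, 4, 4), df_residual = 220
  ), class = "constancy_fit")
  pr <- predict_future(fit, smd_dl = 0.5, year_diff = 20, year_last = 2018)
  hand <- 36.14 + 0.88 * 0.5 - 0.009 * 20 - 0.018 * 2018
  expect_equal(pr$prediction, hand, tolerance = 1e-12)
  expect_error(predict_future(fit, smd_dl = 0.5, year_diff = 20),
               "year_last")
})

test_that("prediction passes through the weighted mean and leverage grows outward", {
  rows <- make_rows(100, noise_sd = 0.2, seed = 4)
  fit <- fit_wls(rows, "smd_dl")
  xbar <- weighted.mean(rows$smd_dl, rows$weight)
  ybar <- weighted.mean(rows$smd_lt, rows$weight)
  at_mean <- predict_future(fit, smd_dl = xbar)
  expect_equal(at_mean$prediction, ybar, tolerance = 1e-10)
  widths <- vapply(c(0, 0.5, 1, 2), function(step) {
    p <- predict_future(fit, smd_dl = xbar + step)
    p$pi_high - p$pi_low
  }, numeric(1))
  expect_true(all(diff(widths) > 0))
})

test_that("the discount factor is one minus the historical-SMD slope", {
  rows <- make_rows(50, noise_sd = 0)
  fit <- fit_wls(rows, "smd_dl")
  expect_equal(ni_discount(fit), 1 - 0.9, tolerance = 1e-8)
  fit$coefficients$estimate[2] <- 0.88
  expect_equal(ni_discount(fit), 0.12, tolerance = 1e-12)
  fit$coefficients$estimate[2] <- 1
  expect_equal(ni_discount(fit), 0)
  fit$coefficients$term[2] <- "something_else"
  expect_error(ni_discount(fit), "historical-SMD")
})
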
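#' Regression rows from recency splits
#'
#' Assembles the review-level dataset for the constancy regression: the
#' last set's pooled SMD as the response, the historical pooled SMD as the
#' predictor, the year span of the historical set and the year of the last
#' trial(s) as candidate covariates, and the historical meta-analysis's
#' total sample size as the weight. Only eligible reviews (at least 4
#' trials, at least 3 historical) contribute rows.
#'
#' @param x A \code{recency_split_list} or list of \code{recency_split}.
#' @param year_diff_all Use the year span over all trials instead of over
#'   the historical set (default \code{FALSE}; the historical-set span is
#'   the regression default).
#' @return List with \code{rows} (data frame: \code{review_id},
#'   \code{smd_lt}, \code{smd_dl}, \code{year_diff}, \code{year_last},
#'   \code{weight}) and \code{excluded} (ids of ineligible reviews).
#' @export
regression_rows <- function(x, year_diff_all = FALSE) {
  splits <- if (inherits(x, "recency_split_list")) x$splits else x
  eligible <- vapply(splits, function(s) s$eligible, logical(1))
  rows <- do.call(rbind, lapply(splits[eligible], function(s) {
    data.frame(
      review_id = s$review_id,
      smd_lt = s$smd_lt$smd,
      smd_dl = s$smd_dl$smd,
      year_diff = if (year_diff_all) s$year_diff_all else s$year_diff,
      year_last = s$year_of_last,
      weight = s$smd_dl$n_total,
      stringsAsFactors = FALSE
    )
  }))
  list(rows = rows,
       excluded = vapply(splits[!eligible], function(s) as.character(s$review_id),
                         character(1)))
}

.covariate_names <- c("smd_dl", "year_diff", "year_last")

#' Weighted least-squares constancy fit
#'
#' Fits the review-level model
#' \deqn{SMD_{lt} = \beta_0 + \beta_1 SMD_{dl} + \beta_2 \, yeardiff +
#'   \beta_3 \, year + \epsilon}
#' (any subset of the three covariates) by weighted least squares, weighted
#' by the total sample size of the historical meta-analysis. Standard
#' errors come from the weighted coefficient covariance, 95\% CIs use the t
#' multiplier on \eqn{n - p - 1} degrees of freedom, and the adjusted
#' \eqn{R^2} is computed on the weighted scale. Calendar year enters
#' uncentered by default; centering changes only the intercept.
#'
#' @param rows Data frame as produced by [regression_rows()]; needs
#'   columns for the requested covariates plus \code{smd_lt} and
#'   \code{weight} (> 0).
#' @param covariates Character subset of
#'   \code{c("smd_dl", "year_diff", "year_last")}.
#' @param center_year Subtract the weighted mean year from
#'   \code{year_last} and \code{year_diff} before fitting (default
#'   \code{FALSE}).
#' @return An object of class \code{constancy_fit}: coefficient table
#'   (\code{coefficients}: term, estimate, se, ci_low, ci_high, p_value),
#'   \code{adj_r2}, \code{n_rows}, \code{selected}, \code{residual_variance}
#'   (weighted), \code{sigma}, \code{df_residual}, \code{median_weight},
#'   \code{vcov}, and the underlying \code{lm} object (\code{fit}).
#' @export
fit_wls <- function(rows, covariates = c("smd_dl", "year_diff", "year_last"),
                    center_year = FALSE) {
  covariates <- match.arg(covariates, .covariate_names, several.ok = TRUE)
  if (any(!is.finite(rows$weight)) || any(rows$weight <= 0)) {
    stop("all weights must be positive")
  }
  p <- length(covariates)
  if (nrow(rows) < p + 1L) {
    stop("need at least ", p + 1L, " rows to fit ", p, " covariates")
  }
  dat <- rows
  if (center_year) {
    for (v in intersect(c("year_last", "year_diff"), covariates)) {
      dat[[v]] <- dat[[v]] - stats::weighted.mean(dat[[v]], dat$weight)
    }
  }
  x <- as.matrix(cbind(`(Intercept)` = 1, dat[covariates]))
  qr_x <- qr(sqrt(dat$weight) * x)
  if (qr_x$rank < ncol(x)) {
    bad <- colnames(x)[qr_x$pivot[(qr_x$rank + 1L):ncol(x)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }

  fm <- stats::as.formula(paste("smd_lt ~", paste(covariates, collapse = " + ")))
  fit <- stats::lm(fm, data = dat, weights = weight)
  # saturated fits (0 residual df) have undefined SEs/CIs; NaNs are expected
  quiet_if_saturated <- if (fit$df.residual == 0L) suppressWarnings else identity
  sm <- quiet_if_saturated(summary(fit))
  ci <- quiet_if_saturated(stats::confint(fit, level = 0.95))
  coefs <- data.frame(
    term = rownames(sm$coefficients),
    estimate = sm$coefficients[, "Estimate"],
    se = sm$coefficients[, "Std. Error"],
    ci_low = ci[, 1], ci_high = ci[, 2],
    p_value = sm$coefficients[, "Pr(>|t|)"],
    row.names = NULL, stringsAsFactors = FALSE
  )

  structure(list(
    coefficients = coefs,
    adj_r2 = sm$adj.r.squared,
    r2 = sm$r.squared,
    n_rows = nrow(dat),
    selected = covariates,
    residual_variance = sm$sigma^2,
    sigma = sm$sigma,
    df_residual = fit$df.residual,
    median_weight = stats::median(dat$weight),
    vcov = stats::vcov(fit),
    center_year = center_year,
    fit = fit
  ), class = "constancy_fit")
}

#' @export
print.constancy_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Weighted least-squares constancy model (n = %d reviews)\n",
              x$n_rows))
  tab <- x$coefficients
  cat(sprintf("  %-14s %10s  [%9s; %9s]  %9s\n",
              "term", "B", "ci_low", "ci_high", "p"))
  for (i in seq_len(nrow(tab))) {
    cat(sprintf("  %-14s %10.*f  [%9.*f; %9.*f]  %9.3g\n",
                tab$term[i], digits, tab$estimate[i], digits, tab$ci_low[i],
                digits, tab$ci_high[i], tab$p_value[i]))
  }
  cat(sprintf("  Adjusted R^2 = %.3f; attenuation (1 - B_smd_dl) = %.3f\n",
              x$adj_r2, ni_discount(x)))
  invisible(x)
}

coef_of <- function(fit, term) {
  i <- match(term, fit$coefficients$term)
  if (is.na(i)) NA_real_ else fit$coefficients$estimate[i]
}

#' Stepwise covariate selection for the constancy model
#'
#' Forward selection with entry at \eqn{p < 0.05} and backward removal at
#' \eqn{p > 0.10}, deterministic given the rows. The historical SMD
#' (\code{smd_dl}) is the model's core predictor and is always included,
#' never subject to removal; only the year covariates are selected over.
#'
#' @inheritParams fit_wls
#' @param candidates Covariates considered for entry, a subset of
#'   \code{c("year_diff", "year_last")}.
#' @param enter Entry p-value threshold (default 0.05).
#' @param remove Removal p-value threshold (default 0.10); must exceed
#'   \code{enter}.
#' @return The final \code{constancy_fit}, with \code{selected} recording
#'   the retained covariates (always including \code{smd_dl}).
#' @export
stepwise_select <- function(rows, candidates = c("year_diff", "year_last"),
                            enter = 0.05, remove = 0.10,
                            center_year = FALSE) {
  if (length(candidates) > 0L) {
    candidates <- match.arg(candidates, c("year_diff", "year_last"),
                            several.ok = TRUE)
  }
  if (!(enter > 0 && enter < remove && remove < 1)) {
    stop("thresholds must satisfy 0 < enter < remove < 1")
  }
  selected <- character(0)
  p_of <- function(fit, term) {
    i <- match(term, fit$coefficients$term)
    p <- fit$coefficients$p_value[i]
    if (is.na(p)) 1 else p            # degenerate (e.g. noiseless) fits
  }
  repeat {
    changed <- FALSE
    # forward step: best candidate with p < enter
    pool <- setdiff(candidates, selected)
    if (length(pool) > 0L) {
      ps <- vapply(pool, function(term) {
        p_of(fit_wls(rows, c("smd_dl", selected, term), center_year), term)
      }, numeric(1))
      if (min(ps) < enter) {
        selected <- c(selected, pool[which.min(ps)])
        changed <- TRUE
      }
    }
    # backward step: worst retained candidate with p > remove
    if (length(selected) > 0L) {
      fit <- fit_wls(rows, c("smd_dl", selected), center_year)
      ps <- vapply(selected, function(term) p_of(fit, term), numeric(1))
      if (max(ps) > remove) {
        selected <- setdiff(selected, selected[which.max(ps)])
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  fit_wls(rows, c("smd_dl", selected), center_year)
}

#' Predict a future trial's SMD
#'
#' Evaluates the fitted constancy model at the supplied covariates, with a
#' 95\% prediction interval combining the residual variance (scaled by the
#' future trial's implied weight, by default the fitted corpus's median
#' weight) and the coefficient covariance at the query point.
#'
#' @param fit A \code{constancy_fit}.
#' @param smd_dl Historical pooled SMD for the future comparison.
#' @param year_diff,year_last Values for the year covariates; required for
#'   every covariate the model retains, ignored otherwise.
#' @param weight Sample-size weight for the predicted trial; default is the
#'   median weight of the fitted rows.
#' @return List with \code{prediction}, \code{pi_low}, \code{pi_high},
#'   \code{se_prediction}.
#' @export
predict_future <- function(fit, smd_dl, year_diff = NULL, year_last = NULL,
                           weight = NULL) {
  vals <- list(smd_dl = smd_dl, year_diff = year_diff, year_last = year_last)
  need <- fit$selected
  miss <- need[vapply(vals[need], is.null, logical(1))]
  if (length(miss) > 0L) {
    stop("missing covariate value(s): ", paste(miss, collapse = ", "))
  }
  x <- c(1, unlist(vals[need], use.names = FALSE))
  beta <- fit$coefficients$estimate
  pred <- sum(x * beta)
  if (is.null(weight)) weight <- fit$median_weight
  var_pred <- fit$residual_variance / weight +
    drop(t(x) %*% fit$vcov %*% x)
  half <- stats::qt(0.975, fit$df_residual) * sqrt(var_pred)
  list(prediction = pred, pi_low = pred - half, pi_high = pred + half,
       se_prediction = sqrt(var_pred))
}

#' Noninferiority discount factor
#'
#' The proportional attenuation of a historical meta-analytic effect when
#' carried forward to a new trial: \eqn{1 - \beta_{SMDdl}}. A slope of 1
#' means perfect constancy (no discount); a slope of 0.88 means a future
#' trial is expected to show an effect 12\% smaller than the historical
#' meta-analysis, and a putative-placebo noninferiority margin built from
#' that meta-analysis should be discounted accordingly.
#'
#' @param fit A \code{constancy_fit} including the \code{smd_dl} term.
#' @return The attenuation factor, a single number.
#' @export
ni_discount <- function(fit) {
  b <- coef_of(fit, "smd_dl")
  if (is.na(b)) stop("fit does not include the historical-SMD term")
  1 - b
}
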
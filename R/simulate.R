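#' Simulation configuration
#'
#' Parameters of the synthetic-corpus generator. Defaults emulate a corpus
#' of placebo-controlled meta-analyses extracted from systematic reviews:
#' 236 reviews of 4-51 trials (median 7, mean 9.9, via a shifted negative
#' binomial), publication years spanning 1931-2016, about 68\% binary
#' outcomes, about 65\% harm-direction outcomes, lognormal arm sizes
#' growing weakly with year, and configurable linear drift in the true
#' treatment effect and in the placebo response.
#'
#' @param n_reviews Number of reviews (meta-analyses).
#' @param trials_min Minimum trials per review; the count is
#'   \code{trials_min + NegBin(trials_nb_size, mu = trials_nb_mu)}.
#' @param trials_nb_size,trials_nb_mu Negative-binomial dispersion and mean
#'   of the excess over \code{trials_min}. The defaults (0.55, 5.9) give
#'   median 7, mean 9.9 and an expected maximum near 51 in a 236-review
#'   corpus.
#' @param year_range Two calendar years, the corpus time span.
#' @param review_span Mean width (years) of the window a single review's
#'   trials fall in; widths are exponential with this mean (truncated to
#'   the corpus range, minimum 1), so most reviews span one or two decades
#'   while a few span most of the corpus era. Windows are placed uniformly
#'   inside \code{year_range}.
#' @param effect_drift Change in the true benefit-positive SMD per year
#'   (0 = constancy holds).
#' @param placebo_drift Change in the placebo response per year: raw
#'   outcome units for continuous outcomes (outcome SD is 1), logit units
#'   for binary outcomes.
#' @param base_effect_mean,base_effect_sd Distribution of the review-level
#'   true SMD at the start of \code{year_range}.
#' @param tau Between-trial SD of the true effect within a review.
#' @param arm_size_meanlog,arm_size_sdlog Lognormal per-arm size at the
#'   start of \code{year_range}; \code{arm_size_sdlog} is the trial-level
#'   spread within a review.
#' @param arm_size_rev_sdlog SD of the review-level log size factor:
#'   trials within a review share a size scale (large-trial fields vs
#'   small-trial fields), which is what makes review totals span two
#'   orders of magnitude.
#' @param arm_size_growth Growth of \code{arm_size_meanlog} per year
#'   (weakly positive by default).
#' @param arm_size_min Lower clamp on the per-arm size.
#' @param prop_binary Proportion of reviews with a binary outcome.
#' @param harm_fraction Proportion of reviews measuring a harm-direction
#'   outcome.
#' @param placebo_base_prob Baseline placebo event probability for binary
#'   outcomes, in (0, 1).
#' @param placebo_base_mean Baseline placebo mean for continuous outcomes.
#' @param seed Integer seed; every draw in the generator flows from it.
#' @return A list of class \code{sim_config}.
#' @export
sim_config <- function(n_reviews = 236,
                       trials_min = 4L,
                       trials_nb_size = 0.55,
                       trials_nb_mu = 5.9,
                       year_range = c(1931L, 2016L),
                       review_span = 20,
                       effect_drift = 0,
                       placebo_drift = 0,
                       base_effect_mean = 0.3,
                       base_effect_sd = 0.3,
                       tau = 0.15,
                       arm_size_meanlog = log(70),
                       arm_size_sdlog = 0.35,
                       arm_size_rev_sdlog = 0.65,
                       arm_size_growth = 0.002,
                       arm_size_min = 10L,
                       prop_binary = 0.68,
                       harm_fraction = 0.654,
                       placebo_base_prob = 0.30,
                       placebo_base_mean = 0,
                       seed = 1L) {
  cfg <- as.list(environment())
  if (cfg$n_reviews < 1) stop("invalid n_reviews: must be >= 1")
  if (diff(range(cfg$year_range)) < 1) stop("invalid year_range: must span > 0 years")
  if (cfg$tau < 0) stop("invalid tau: must be >= 0")
  if (cfg$trials_nb_size <= 0 || cfg$trials_nb_mu <= 0) {
    stop("invalid trials_nb_size/trials_nb_mu: must be > 0")
  }
  for (p in c("prop_binary", "harm_fraction")) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) stop("invalid ", p, ": must be in [0, 1]")
  }
  if (cfg$placebo_base_prob <= 0 || cfg$placebo_base_prob >= 1) {
    stop("invalid placebo_base_prob: must be in (0, 1)")
  }
  if (cfg$arm_size_sdlog < 0 || cfg$arm_size_rev_sdlog < 0 ||
      cfg$base_effect_sd < 0) {
    stop("invalid arm_size_sdlog/arm_size_rev_sdlog/base_effect_sd: must be >= 0")
  }
  structure(cfg, class = "sim_config")
}

#' Simulate a corpus of placebo-controlled meta-analyses
#'
#' Generates trial-level per-arm summaries whose implied SMD is centered on
#' each trial's true effect with the correct sampling distribution.
#' For review j, a base effect \eqn{\theta_j} is drawn; trial i in year t
#' has true benefit-positive effect
#' \eqn{\theta_j + \delta (t - t_0) + u_i}, \eqn{u_i \sim N(0, \tau^2)},
#' with \eqn{t_0} the start of the year range and \eqn{\delta} the effect
#' drift. Continuous outcomes draw arm means from their normal sampling
#' distribution (unit outcome SD) and arm SDs from the scaled chi-square;
#' binary outcomes place the placebo probability on the logit scale and set
#' the active arm's log odds ratio to \eqn{d \pi / \sqrt 3}, so the true
#' SMD under the log-odds-ratio mapping is exact. Harm-direction reviews
#' have the raw effect sign flipped, which direction harmonization undoes
#' downstream.
#'
#' A single root seed drives per-review child seeds, so the corpus is
#' reproducible and individual reviews can be regenerated independently.
#'
#' @param config A [sim_config()].
#' @return A list of class \code{sim_corpus}: \code{trials} (trial-level
#'   data frame, see [trial_columns]), \code{truth} (review-level
#'   \code{theta} and a per-trial data frame with every latent value), and
#'   \code{config}.
#' @export
simulate_corpus <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  child_seeds <- sample.int(.Machine$integer.max - 1L, config$n_reviews)
  t0 <- config$year_range[1]
  max_span <- diff(config$year_range)

  reviews <- lapply(seq_len(config$n_reviews), function(j) {
    set.seed(child_seeds[j])
    k <- config$trials_min + stats::rnbinom(1, size = config$trials_nb_size,
                                            mu = config$trials_nb_mu)
    binary <- stats::runif(1) < config$prop_binary
    harm <- stats::runif(1) < config$harm_fraction
    measure <- if (binary) {
      sample(c("RR", "OR", "RD"), 1, prob = c(0.553, 0.114, 0.012))
    } else "MD"
    theta <- stats::rnorm(1, config$base_effect_mean, config$base_effect_sd)

    span <- min(max(1L, round(stats::rexp(1, 1 / config$review_span))),
                max_span)
    win_start <- floor(stats::runif(1, t0, config$year_range[2] - span + 1))
    years <- win_start + sample.int(span + 1L, k, replace = TRUE) - 1L
    if (length(unique(years)) < 2L) {       # a split needs >= 2 distinct years
      years[1] <- if (years[1] > t0) years[1] - 1L else years[1] + 1L
    }

    d_true <- theta + config$effect_drift * (years - t0) +
      stats::rnorm(k, 0, config$tau)
    raw_sign <- if (harm) -1 else 1
    size_factor <- stats::rnorm(1, 0, config$arm_size_rev_sdlog)
    n_arm <- pmax(config$arm_size_min,
                  round(stats::rlnorm(k,
                                      config$arm_size_meanlog + size_factor +
                                        config$arm_size_growth * (years - t0),
                                      config$arm_size_sdlog)))

    tr <- data.frame(
      review_id = sprintf("R%04d", j),
      trial_id = sprintf("R%04d_T%02d", j, seq_len(k)),
      pub_year = years,
      outcome_kind = if (binary) "binary" else "continuous",
      direction = if (harm) "harm" else "benefit",
      declared_measure = measure,
      active_n = n_arm, placebo_n = n_arm,
      active_mean = NA_real_, active_sd = NA_real_,
      placebo_mean = NA_real_, placebo_sd = NA_real_,
      active_events = NA_real_, placebo_events = NA_real_,
      stringsAsFactors = FALSE
    )

    if (binary) {
      logit_p0 <- stats::qlogis(config$placebo_base_prob) +
        config$placebo_drift * (years - t0)
      p_placebo <- stats::plogis(logit_p0)
      p_active <- stats::plogis(logit_p0 + raw_sign * d_true * pi / sqrt(3))
      tr$active_events <- stats::rbinom(k, n_arm, p_active)
      tr$placebo_events <- stats::rbinom(k, n_arm, p_placebo)
    } else {
      mu_placebo <- config$placebo_base_mean +
        config$placebo_drift * (years - t0)
      mu_active <- mu_placebo + raw_sign * d_true
      tr$placebo_mean <- stats::rnorm(k, mu_placebo, 1 / sqrt(n_arm))
      tr$active_mean <- stats::rnorm(k, mu_active, 1 / sqrt(n_arm))
      tr$placebo_sd <- sqrt(stats::rchisq(k, n_arm - 1) / (n_arm - 1))
      tr$active_sd <- sqrt(stats::rchisq(k, n_arm - 1) / (n_arm - 1))
    }
    list(trials = tr,
         truth = data.frame(review_id = tr$review_id, trial_id = tr$trial_id,
                            theta = theta, true_effect = d_true,
                            stringsAsFactors = FALSE))
  })

  structure(list(
    trials = do.call(rbind, lapply(reviews, `[[`, "trials")),
    truth = list(
      theta = vapply(reviews, function(r) r$truth$theta[1], numeric(1)),
      trials = do.call(rbind, lapply(reviews, `[[`, "truth"))
    ),
    config = config
  ), class = "sim_corpus")
}

#' @export
print.sim_corpus <- function(x, ...) {
  cat(sprintf(
    "Synthetic corpus: %d reviews, %d trials, years %d-%d (seed %d)\n",
    length(unique(x$trials$review_id)), nrow(x$trials),
    min(x$trials$pub_year), max(x$trials$pub_year), x$config$seed
  ))
  invisible(x)
}

#' Simulate review-level regression rows
#'
#' Direct generator for the constancy regression: covariates are drawn from
#' stated distributions and the response is the linear combination plus
#' Gaussian noise whose variance is \eqn{\sigma^2 \cdot \tilde w / w_i}
#' (\eqn{\tilde w} the median weight), so sample-size weighting is the
#' correctly specified model. Weights enter only relatively: rescaling all
#' weights leaves the response distribution unchanged.
#'
#' @param coefficients Named numeric vector with \code{intercept} and any of
#'   \code{smd_dl}, \code{year_diff}, \code{year_last}; omitted terms have
#'   generating coefficient 0 (their covariates are still drawn, so they
#'   can serve as null candidates in selection tests).
#' @param n_rows Number of reviews to generate; must exceed the number of
#'   coefficients plus 2.
#' @param noise_sd Residual SD at the median weight (>= 0).
#' @param covariate_dists List of distribution parameters:
#'   \code{smd_dl = c(mean, sd)} (normal),
#'   \code{year_diff = c(min, max)} and \code{year_last = c(min, max)}
#'   (uniform), \code{weight = c(meanlog, sdlog)} (lognormal; default
#'   median 1160).
#' @param seed Integer seed.
#' @return List with \code{rows} (data frame ready for [fit_wls()]) and
#'   \code{truth} (the generating coefficients and noise SD).
#' @export
simulate_regression_rows <- function(coefficients = c(intercept = 36.14,
                                                      smd_dl = 0.88,
                                                      year_diff = -0.009,
                                                      year_last = -0.018),
                                     n_rows = 500,
                                     noise_sd = 0.2,
                                     covariate_dists = list(
                                       smd_dl = c(mean = 0.3, sd = 0.3),
                                       year_diff = c(min = 1, max = 40),
                                       year_last = c(min = 1990, max = 2016),
                                       weight = c(meanlog = log(1160), sdlog = 1)
                                     ),
                                     seed = 1L) {
  if (!"intercept" %in% names(coefficients)) {
    stop("coefficients must include an 'intercept' term")
  }
  extra <- setdiff(names(coefficients), c("intercept", .covariate_names))
  if (length(extra) > 0L) {
    stop("unknown coefficient name(s): ", paste(extra, collapse = ", "))
  }
  if (n_rows <= length(coefficients) + 2L) {
    stop("n_rows must exceed the number of coefficients plus 2")
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  d <- covariate_dists
  if (d$smd_dl[["sd"]] < 0 || d$weight[["sdlog"]] < 0 ||
      d$year_diff[["min"]] > d$year_diff[["max"]] ||
      d$year_last[["min"]] > d$year_last[["max"]]) {
    stop("invalid covariate distribution spec")
  }

  set.seed(seed)
  rows <- data.frame(
    review_id = sprintf("S%05d", seq_len(n_rows)),
    smd_dl = stats::rnorm(n_rows, d$smd_dl[["mean"]], d$smd_dl[["sd"]]),
    year_diff = stats::runif(n_rows, d$year_diff[["min"]], d$year_diff[["max"]]),
    year_last = stats::runif(n_rows, d$year_last[["min"]], d$year_last[["max"]]),
    weight = stats::rlnorm(n_rows, d$weight[["meanlog"]], d$weight[["sdlog"]]),
    stringsAsFactors = FALSE
  )
  beta <- function(term) if (term %in% names(coefficients)) coefficients[[term]] else 0
  mu <- coefficients[["intercept"]] +
    beta("smd_dl") * rows$smd_dl +
    beta("year_diff") * rows$year_diff +
    beta("year_last") * rows$year_last
  sd_i <- noise_sd * sqrt(stats::median(rows$weight) / rows$weight)
  rows$smd_lt <- mu + stats::rnorm(n_rows, 0, sd_i)
  rows <- rows[, c("review_id", "smd_lt", "smd_dl", "year_diff",
                   "year_last", "weight")]
  list(rows = rows,
       truth = list(coefficients = coefficients, noise_sd = noise_sd,
                    seed = seed))
}
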
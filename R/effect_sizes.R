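#' Standardized mean difference for a continuous outcome
#'
#' Cohen's d with the pooled standard deviation, optionally with Hedges'
#' small-sample correction \eqn{J = 1 - 3 / (4 \, df - 1)} where
#' \eqn{df = n_a + n_p - 2}. The sampling variance is
#' \eqn{(n_a + n_p) / (n_a n_p) + d^2 / (2 (n_a + n_p))} evaluated at the
#' returned (possibly corrected) estimate, and the 95\% CI uses the normal
#' 1.96 multiplier.
#'
#' The sign convention is raw: a higher active-arm mean gives a positive
#' SMD. Orientation to the benefit-positive scale is a separate step
#' ([harmonize_direction()]).
#'
#' All arguments are vectorized.
#'
#' @param active_mean,active_sd,active_n Active-arm mean, SD (> 0), size
#'   (>= 2).
#' @param placebo_mean,placebo_sd,placebo_n Placebo-arm summaries, same
#'   constraints.
#' @param hedges Apply the small-sample correction (default \code{TRUE}).
#' @return Data frame of class \code{effect_estimate} with columns
#'   \code{smd}, \code{var}, \code{ci_low}, \code{ci_high}, \code{n_total}.
#' @examples
#' smd_continuous(12, 4, 50, 10, 4, 50, hedges = FALSE)
#' @export
smd_continuous <- function(active_mean, active_sd, active_n,
                           placebo_mean, placebo_sd, placebo_n,
                           hedges = TRUE) {
  if (any(active_sd <= 0, na.rm = TRUE)) stop("active arm: sd must be > 0")
  if (any(placebo_sd <= 0, na.rm = TRUE)) stop("placebo arm: sd must be > 0")
  if (any(active_n < 2, na.rm = TRUE)) stop("active arm: n must be >= 2")
  if (any(placebo_n < 2, na.rm = TRUE)) stop("placebo arm: n must be >= 2")

  df <- active_n + placebo_n - 2
  s_pooled <- sqrt(((active_n - 1) * active_sd^2 +
                      (placebo_n - 1) * placebo_sd^2) / df)
  d <- (active_mean - placebo_mean) / s_pooled
  if (hedges) {
    d <- d * (1 - 3 / (4 * df - 1))
  }
  n_total <- active_n + placebo_n
  v <- n_total / (active_n * placebo_n) + d^2 / (2 * n_total)
  new_effect(d, v, n_total)
}

#' Standardized mean difference for a binary outcome
#'
#' Converts a 2x2 table to the SMD scale through the log odds ratio:
#' \eqn{d = \ln(OR) \sqrt{3} / \pi}, with
#' \eqn{Var(d) = Var(\ln OR) \cdot 3 / \pi^2} and \eqn{Var(\ln OR)} the sum
#' of reciprocal cell counts. When any cell of a table is zero, 0.5 is
#' added to all four cells of that table before computation.
#'
#' The SMD is positive when the active arm has higher odds of the raw
#' event; direction harmonization is a separate step.
#'
#' All arguments are vectorized.
#'
#' @param active_events,active_n Active-arm events and size.
#' @param placebo_events,placebo_n Placebo-arm events and size.
#' @return Data frame of class \code{effect_estimate} (see
#'   [smd_continuous()]).
#' @examples
#' smd_binary(30, 100, 20, 100)
#' @export
smd_binary <- function(active_events, active_n, placebo_events, placebo_n) {
  if (any(active_n < 1, na.rm = TRUE) || any(placebo_n < 1, na.rm = TRUE)) {
    stop("arm sizes must be >= 1")
  }
  if (any(active_events < 0 | active_events > active_n, na.rm = TRUE) ||
      any(placebo_events < 0 | placebo_events > placebo_n, na.rm = TRUE)) {
    stop("event counts must lie in [0, arm n]")
  }
  a <- active_events
  b <- active_n - active_events
  c_ <- placebo_events
  d_ <- placebo_n - placebo_events
  zero <- a == 0 | b == 0 | c_ == 0 | d_ == 0
  cc <- ifelse(zero, 0.5, 0)
  a <- a + cc; b <- b + cc; c_ <- c_ + cc; d_ <- d_ + cc

  lnor <- log((a * d_) / (b * c_))
  v_lnor <- 1 / a + 1 / b + 1 / c_ + 1 / d_
  smd <- lnor * sqrt(3) / pi
  v <- v_lnor * 3 / pi^2
  new_effect(smd, v, active_n + placebo_n)
}

new_effect <- function(smd, var, n_total) {
  half <- 1.96 * sqrt(var)
  out <- data.frame(smd = smd, var = var,
                    ci_low = smd - half, ci_high = smd + half,
                    n_total = n_total)
  class(out) <- c("effect_estimate", "data.frame")
  out
}

#' Orient an effect estimate to the benefit-positive scale
#'
#' Reviews measure both beneficial outcomes (healing, improvement) and
#' harmful ones (death, relapse, pain). To put every effect on one scale,
#' estimates from harm-direction outcomes are flipped so that a positive
#' SMD always means the active arm did better: the SMD and CI bounds are
#' negated (bounds swapped); the variance is unchanged. Benefit-direction
#' estimates pass through untouched.
#'
#' @param effects An \code{effect_estimate} data frame.
#' @param direction \code{"benefit"} or \code{"harm"}, recycled to
#'   \code{nrow(effects)}.
#' @return The harmonized \code{effect_estimate}.
#' @export
harmonize_direction <- function(effects, direction) {
  if (!all(direction %in% .directions)) {
    stop("direction must be 'benefit' or 'harm'")
  }
  flip <- rep_len(direction == "harm", nrow(effects))
  lo <- ifelse(flip, -effects$ci_high, effects$ci_low)
  hi <- ifelse(flip, -effects$ci_low, effects$ci_high)
  effects$smd <- ifelse(flip, -effects$smd, effects$smd)
  effects$ci_low <- lo
  effects$ci_high <- hi
  effects
}

#' Per-trial effect estimates for a corpus
#'
#' Computes an SMD with sampling variance for every trial in a corpus,
#' routing continuous outcomes through [smd_continuous()] and binary
#' outcomes (whatever their declared source measure) through
#' [smd_binary()], then optionally orienting each estimate to the
#' benefit-positive scale.
#'
#' @param trials Trial-level data frame (see [trial_columns]).
#' @param hedges Small-sample correction for continuous outcomes.
#' @param harmonize Orient to benefit-positive (default \code{TRUE}).
#' @return The input with columns \code{smd}, \code{var}, \code{ci_low},
#'   \code{ci_high}, \code{n_total} appended.
#' @export
trial_effects <- function(trials, hedges = TRUE, harmonize = TRUE) {
  n <- nrow(trials)
  eff <- new_effect(rep(NA_real_, n), rep(NA_real_, n),
                    trials$active_n + trials$placebo_n)
  cont <- trials$outcome_kind == "continuous"
  if (any(cont)) {
    eff[cont, ] <- smd_continuous(
      trials$active_mean[cont], trials$active_sd[cont], trials$active_n[cont],
      trials$placebo_mean[cont], trials$placebo_sd[cont], trials$placebo_n[cont],
      hedges = hedges
    )
  }
  if (any(!cont)) {
    eff[!cont, ] <- smd_binary(
      trials$active_events[!cont], trials$active_n[!cont],
      trials$placebo_events[!cont], trials$placebo_n[!cont]
    )
  }
  if (harmonize) {
    eff <- harmonize_direction(eff, trials$direction)
  }
  cbind(trials, eff)
}
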
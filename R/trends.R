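.trend_vars <- c("smd", "placebo", "active", "n")

.categories <- c("strong_negative", "moderate_negative", "weak_negative",
                 "weak_positive", "moderate_positive", "strong_positive")

#' Classify a correlation coefficient
#'
#' Strength bands on \eqn{|r|}: weak below 0.3, moderate in
#' \eqn{[0.3, 0.5]}, strong above 0.5; the sign of \eqn{r} is kept, giving
#' six categories. \eqn{r = 0} is classed as \code{weak_positive} by
#' convention.
#'
#' @param r Numeric vector of correlations in \eqn{[-1, 1]}.
#' @return Factor with levels \code{strong_negative} ...
#'   \code{strong_positive}; \code{NA} in gives \code{NA} out.
#' @examples
#' classify_correlation(c(0.1, -0.6, 0.5))
#' @export
classify_correlation <- function(r) {
  if (any(abs(r) > 1, na.rm = TRUE)) stop("|r| must be <= 1")
  strength <- ifelse(abs(r) < 0.3, "weak",
                     ifelse(abs(r) <= 0.5, "moderate", "strong"))
  sign_lab <- ifelse(r < 0, "negative", "positive")
  factor(ifelse(is.na(r), NA, paste(strength, sign_lab, sep = "_")),
         levels = .categories)
}

safe_cor <- function(x, y, method) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y, method = method)
}

#' Per-review time trends
#'
#' Pearson and Spearman correlations of publication year against the
#' benefit-positive per-trial SMD, the raw placebo response, the raw active
#' response, and the total sample size, for one review. SMDs are oriented
#' to the benefit-positive scale before correlating; arm responses are
#' left on the raw outcome scale.
#'
#' A correlation is undefined (\code{NA}, \code{defined = FALSE}) when
#' either series is constant. At least 3 trials spanning at least 2
#' distinct years are required; with fewer, a correlation is always
#' \eqn{\pm 1} and would distort category counts.
#'
#' @param trials Trial-level data frame for a single review.
#' @param hedges Small-sample correction passed to [trial_effects()].
#' @param min_trials Minimum trials required (default 3).
#' @return One-row data frame with \code{review_id}; \code{r_smd},
#'   \code{r_placebo}, \code{r_active}, \code{r_n} (Pearson) and their
#'   \code{rs_*} Spearman twins; \code{category_smd},
#'   \code{category_placebo}, \code{category_active}; and \code{defined_*}
#'   flags.
#' @export
review_trend <- function(trials, hedges = TRUE, min_trials = 3L) {
  rid <- unique(trials$review_id)
  if (length(rid) != 1L) stop("trials must all belong to one review")
  if (nrow(trials) < min_trials) {
    stop("review ", rid, ": at least ", min_trials,
         " trials are required for a trend correlation")
  }
  if (length(unique(trials$pub_year)) < 2L) {
    stop("review ", rid, ": trends need at least 2 distinct years")
  }
  eff <- trial_effects(trials, hedges = hedges, harmonize = TRUE)
  resp <- arm_responses(trials)
  year <- trials$pub_year
  series <- list(smd = eff$smd, placebo = resp$placebo_response,
                 active = resp$active_response, n = eff$n_total)

  out <- data.frame(review_id = rid, stringsAsFactors = FALSE)
  for (v in .trend_vars) {
    r_p <- safe_cor(year, series[[v]], "pearson")
    r_s <- safe_cor(year, series[[v]], "spearman")
    out[[paste0("r_", v)]] <- r_p
    out[[paste0("rs_", v)]] <- r_s
    out[[paste0("defined_", v)]] <- !is.na(r_p)
    if (v != "n") {
      out[[paste0("category_", v)]] <- classify_correlation(r_p)
    }
  }
  out
}

#' Per-review trends for a whole corpus
#'
#' Applies [review_trend()] to every review with enough trials and distinct
#' years; reviews failing the preconditions are skipped and reported.
#'
#' @param trials Trial-level corpus data frame.
#' @inheritParams review_trend
#' @return List with \code{trends} (data frame, one row per usable review)
#'   and \code{skipped} (character vector of review ids).
#' @export
corpus_trends <- function(trials, hedges = TRUE, min_trials = 3L) {
  by_review <- split(trials, factor(trials$review_id,
                                    levels = unique(trials$review_id)))
  usable <- vapply(by_review, function(d) {
    nrow(d) >= min_trials && length(unique(d$pub_year)) >= 2L
  }, logical(1))
  trends <- do.call(rbind, lapply(by_review[usable], review_trend,
                                  hedges = hedges, min_trials = min_trials))
  rownames(trends) <- NULL
  list(trends = trends, skipped = names(by_review)[!usable])
}

#' Aggregate trend correlations across reviews
#'
#' For each variable (SMD, placebo response, active response, sample size)
#' summarizes the per-review Pearson correlations: percent negative,
#' median, mean with a t-based 95\% CI across reviews, and counts per
#' six-level strength/sign category. Undefined correlations are excluded
#' from denominators and their count reported.
#'
#' @param trends Data frame from [corpus_trends()] (or a row-bound set of
#'   [review_trend()] outputs) with at least 2 defined correlations per
#'   variable.
#' @param fisher_z Average on the Fisher z scale instead of plain r
#'   (default \code{FALSE}: plain means of r, back-transformed CIs are not
#'   produced).
#' @return A list of class \code{trend_report}: per variable a list with
#'   \code{n}, \code{n_undefined}, \code{pct_negative}, \code{median},
#'   \code{mean}, \code{ci_low}, \code{ci_high}; plus \code{categories}, a
#'   6 x 3 count table (SMD / placebo / active) in the six-category layout.
#' @export
aggregate_trends <- function(trends, fisher_z = FALSE) {
  per_var <- lapply(.trend_vars, function(v) {
    r <- trends[[paste0("r_", v)]]
    n_undef <- sum(is.na(r))
    r <- r[!is.na(r)]
    if (length(r) < 2L) stop("need at least 2 defined correlations for '", v, "'")
    x <- if (fisher_z) atanh(pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)) else r
    m <- mean(x)
    half <- stats::qt(0.975, length(x) - 1) * stats::sd(x) / sqrt(length(x))
    ci <- c(m - half, m + half)
    if (fisher_z) {
      m <- tanh(m); ci <- tanh(ci)
    }
    list(n = length(r), n_undefined = n_undef,
         pct_negative = 100 * mean(r < 0),
         median = stats::median(r), mean = m,
         ci_low = ci[1], ci_high = ci[2])
  })
  names(per_var) <- .trend_vars

  cats <- sapply(c("smd", "placebo", "active"), function(v) {
    table(trends[[paste0("category_", v)]])
  })
  colnames(cats) <- c("SMD", "placebo", "active")

  structure(c(per_var, list(categories = cats, fisher_z = fisher_z)),
            class = "trend_report")
}

#' @export
print.trend_report <- function(x, ...) {
  labels <- c(smd = "SMD", placebo = "placebo response",
              active = "active response", n = "sample size")
  cat("Correlation of publication year with:\n")
  for (v in .trend_vars) {
    s <- x[[v]]
    cat(sprintf(
      "  %-16s n = %d (%d undefined), %.1f%% negative, median %.3f, mean %.3f [%.3f; %.3f]\n",
      labels[v], s$n, s$n_undefined, s$pct_negative, s$median, s$mean,
      s$ci_low, s$ci_high
    ))
  }
  cat("\nCategory counts:\n")
  print(x$categories)
  invisible(x)
}
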
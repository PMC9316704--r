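#' Pool standardized mean differences
#'
#' Inverse-variance pooling of per-trial SMDs, either under a common-effect
#' ("fixed") model with weights \eqn{1/v_i}, or under the
#' DerSimonian-Laird random-effects model with
#' \eqn{\tau^2 = \max(0, (Q - df) / C)}, \eqn{C = \sum w - \sum w^2 / \sum w}
#' and weights \eqn{1/(v_i + \tau^2)}. Heterogeneity is summarized by
#' Cochran's Q and \eqn{I^2 = \max(0, (Q - df)/Q) \cdot 100}.
#'
#' @param effects An \code{effect_estimate} data frame (columns \code{smd},
#'   \code{var}, \code{n_total}) with at least one row and all variances
#'   positive.
#' @param method \code{"random_dl"} (default) or \code{"fixed"}.
#' @return An object of class \code{pooled_smd}: a list with \code{smd},
#'   \code{se}, \code{ci_low}, \code{ci_high}, \code{k}, \code{n_total},
#'   \code{q}, \code{tau2}, \code{i2}, \code{method}.
#' @export
pool_smd <- function(effects, method = c("random_dl", "fixed")) {
  method <- match.arg(method)
  y <- effects$smd
  v <- effects$var
  k <- length(y)
  if (k == 0L) stop("cannot pool an empty set of effects")
  if (any(!is.finite(v)) || any(v <= 0)) stop("all sampling variances must be > 0")

  w <- 1 / v
  mu_fixed <- sum(w * y) / sum(w)
  q <- sum(w * (y - mu_fixed)^2)
  df <- k - 1
  if (df > 0) {
    c_dl <- sum(w) - sum(w^2) / sum(w)
    tau2 <- max(0, (q - df) / c_dl)
    i2 <- if (q > 0) max(0, (q - df) / q) * 100 else 0
  } else {
    tau2 <- 0
    i2 <- 0
  }

  if (method == "fixed") {
    w_star <- w
  } else {
    w_star <- 1 / (v + tau2)
  }
  mu <- sum(w_star * y) / sum(w_star)
  se <- sqrt(1 / sum(w_star))

  structure(list(
    smd = mu, se = se,
    ci_low = mu - 1.96 * se, ci_high = mu + 1.96 * se,
    k = k, n_total = sum(effects$n_total),
    q = q, tau2 = tau2, i2 = i2, method = method
  ), class = "pooled_smd")
}

#' @export
print.pooled_smd <- function(x, ...) {
  cat(sprintf(
    "Pooled SMD (%s): %.4f [%.4f; %.4f], k = %d, n = %d\n  Q = %.3f, tau^2 = %.4f, I^2 = %.1f%%\n",
    x$method, x$smd, x$ci_low, x$ci_high, x$k, x$n_total, x$q, x$tau2, x$i2
  ))
  invisible(x)
}

#' Split a review into historical and most-recent components
#'
#' Partitions one review's trials by publication year: the "last set" is
#' every trial tied at the maximum year (year ties form a joint last set);
#' the remainder is the historical ("deleted-last", dl) set. Three pooled
#' SMDs are computed on benefit-positive effects: over all trials
#' (\code{smd_all}), over the historical set (\code{smd_dl}), and over the
#' last set (\code{smd_lt}).
#'
#' A review is eligible for the constancy regression when it has at least
#' 4 trials in total and at least 3 remain after deleting the last set;
#' ineligible reviews are flagged, not dropped. Reviews whose trials all
#' share one publication year are excluded by construction (error).
#'
#' @param trials Trial-level data frame for a single review (all rows
#'   sharing \code{review_id}), with at least 2 distinct publication years.
#' @param method Pooling model passed to [pool_smd()].
#' @param hedges Small-sample correction passed to [trial_effects()].
#' @return An object of class \code{recency_split}: a list with
#'   \code{review_id}, \code{smd_all}, \code{smd_dl}, \code{smd_lt}
#'   (\code{pooled_smd} objects), \code{first_year}, \code{last_year},
#'   \code{year_of_last}, \code{year_diff} (span of the historical set),
#'   \code{year_diff_all} (span of all trials), \code{k_all}, \code{k_dl},
#'   \code{k_last}, \code{eligible}.
#' @export
recency_split <- function(trials, method = c("random_dl", "fixed"),
                          hedges = TRUE) {
  method <- match.arg(method)
  rid <- unique(trials$review_id)
  if (length(rid) != 1L) stop("trials must all belong to one review")
  years <- trials$pub_year
  if (length(unique(years)) < 2L) {
    stop("same-year review: all trials share one publication year (review ",
         rid, ")")
  }
  eff <- trial_effects(trials, hedges = hedges, harmonize = TRUE)
  last <- years == max(years)
  dl_years <- years[!last]

  structure(list(
    review_id = rid,
    smd_all = pool_smd(eff, method),
    smd_dl = pool_smd(eff[!last, , drop = FALSE], method),
    smd_lt = pool_smd(eff[last, , drop = FALSE], method),
    first_year = min(years),
    last_year = max(years),
    year_of_last = max(years),
    year_diff = max(dl_years) - min(dl_years),
    year_diff_all = max(years) - min(years),
    k_all = length(years),
    k_dl = sum(!last),
    k_last = sum(last),
    eligible = length(years) >= 4L && sum(!last) >= 3L
  ), class = "recency_split")
}

#' @export
print.recency_split <- function(x, ...) {
  cat(sprintf(
    "Review %s: k = %d (%d historical + %d last, year %d), %s\n",
    x$review_id, x$k_all, x$k_dl, x$k_last, x$year_of_last,
    if (x$eligible) "eligible" else "not eligible"
  ))
  cat(sprintf("  SMD   = %.4f [%.4f; %.4f]\n",
              x$smd_all$smd, x$smd_all$ci_low, x$smd_all$ci_high))
  cat(sprintf("  SMDdl = %.4f [%.4f; %.4f]\n",
              x$smd_dl$smd, x$smd_dl$ci_low, x$smd_dl$ci_high))
  cat(sprintf("  SMDlt = %.4f [%.4f; %.4f]\n",
              x$smd_lt$smd, x$smd_lt$ci_low, x$smd_lt$ci_high))
  invisible(x)
}

#' Recency splits for every review in a corpus
#'
#' Applies [recency_split()] to each review. Reviews with a single distinct
#' publication year are excluded (counted, not erred on) since the split is
#' undefined for them.
#'
#' @param trials Trial-level corpus data frame.
#' @inheritParams recency_split
#' @return A list of class \code{recency_split_list} with elements
#'   \code{splits} (list of \code{recency_split}) and \code{same_year}
#'   (character vector of excluded review ids).
#' @export
split_corpus <- function(trials, method = c("random_dl", "fixed"),
                         hedges = TRUE) {
  method <- match.arg(method)
  by_review <- split(trials, factor(trials$review_id,
                                    levels = unique(trials$review_id)))
  same_year <- vapply(by_review,
                      function(d) length(unique(d$pub_year)) < 2L,
                      logical(1))
  splits <- lapply(by_review[!same_year], recency_split,
                   method = method, hedges = hedges)
  structure(list(splits = unname(splits),
                 same_year = names(by_review)[same_year]),
            class = "recency_split_list")
}

#' Tabulate recency splits
#'
#' One row per review: the three pooled SMDs with their standard errors,
#' the year metadata, trial counts, the historical sample size (the
#' regression weight) and the eligibility flag.
#'
#' @param x A \code{recency_split_list} from [split_corpus()] or a plain
#'   list of \code{recency_split} objects.
#' @return Data frame with one row per split.
#' @export
splits_table <- function(x) {
  splits <- if (inherits(x, "recency_split_list")) x$splits else x
  do.call(rbind, lapply(splits, function(s) {
    data.frame(
      review_id = s$review_id,
      smd_all = s$smd_all$smd, se_all = s$smd_all$se,
      smd_dl = s$smd_dl$smd, se_dl = s$smd_dl$se,
      smd_lt = s$smd_lt$smd, se_lt = s$smd_lt$se,
      i2_all = s$smd_all$i2,
      first_year = s$first_year, last_year = s$last_year,
      year_of_last = s$year_of_last,
      year_diff = s$year_diff, year_diff_all = s$year_diff_all,
      k_all = s$k_all, k_dl = s$k_dl, k_last = s$k_last,
      n_dl = s$smd_dl$n_total,
      eligible = s$eligible,
      stringsAsFactors = FALSE
    )
  }))
}

#' Corpus-level descriptives
#'
#' Counts and summaries across a set of recency splits: number of reviews,
#' trial-count distribution, year range, and eligibility counts.
#'
#' @param x A \code{recency_split_list} or list of \code{recency_split}.
#' @return A list of class \code{corpus_summary}.
#' @export
corpus_summary <- function(x) {
  splits <- if (inherits(x, "recency_split_list")) x$splits else x
  if (length(splits) == 0L) stop("no splits to summarize")
  k <- vapply(splits, function(s) s$k_all, numeric(1))
  structure(list(
    n_reviews = length(splits),
    n_trials = sum(k),
    trials_median = stats::median(k),
    trials_mean = mean(k),
    trials_min = min(k),
    trials_max = max(k),
    year_min = min(vapply(splits, function(s) s$first_year, numeric(1))),
    year_max = max(vapply(splits, function(s) s$last_year, numeric(1))),
    n_eligible = sum(vapply(splits, function(s) s$eligible, logical(1)))
  ), class = "corpus_summary")
}

#' @export
print.corpus_summary <- function(x, ...) {
  cat(sprintf(
    paste0("Corpus: %d reviews, %d trials\n",
           "  trials/review: median %.1f, mean %.2f, range [%d, %d]\n",
           "  years: %d-%d\n  eligible for regression: %d of %d\n"),
    x$n_reviews, x$n_trials, x$trials_median, x$trials_mean,
    x$trials_min, x$trials_max, x$year_min, x$year_max,
    x$n_eligible, x$n_reviews
  ))
  invisible(x)
}
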
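#' Trial-level corpus columns
#'
#' Column names of a trial-level corpus: one row per placebo-controlled
#' trial, with per-arm summaries. Continuous outcomes carry arm means and
#' SDs; binary outcomes carry arm event counts. Exactly one of the two
#' column groups is populated per row.
#'
#' @format Character vector of the 14 required column names.
#' @export
trial_columns <- c(
  "review_id", "trial_id", "pub_year", "outcome_kind", "direction",
  "declared_measure", "active_n", "placebo_n",
  "active_mean", "active_sd", "placebo_mean", "placebo_sd",
  "active_events", "placebo_events"
)

.outcome_kinds <- c("continuous", "binary")
.directions <- c("benefit", "harm")
.measures <- c("MD", "SMD", "RR", "OR", "RD")

#' Validate trial records
#'
#' Checks every row of a trial-level data frame against the corpus
#' invariants: positive arm sizes, positive SDs for continuous outcomes,
#' event counts within \code{[0, n]} for binary outcomes, publication year
#' in \code{[1900, 2100]}, known outcome kind / direction / declared
#' measure, and mutually exclusive population of the continuous and binary
#' column groups.
#'
#' @param trials Data frame with the columns in [trial_columns] (the two
#'   arm-summary groups may be \code{NA} where not applicable).
#' @return A list with \code{valid} (the rows that pass, as supplied) and
#'   \code{rejected} (a data frame with \code{row}, \code{review_id},
#'   \code{trial_id}, \code{reason} for every failing row).
#' @export
validate_trials <- function(trials) {
  missing_cols <- setdiff(trial_columns, names(trials))
  if (length(missing_cols) > 0L) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  n <- nrow(trials)
  reasons <- character(n)
  note <- function(bad, msg) {
    bad <- which(bad)
    reasons[bad] <<- ifelse(reasons[bad] == "", msg, paste(reasons[bad], msg, sep = "; "))
  }

  note(!(trials$outcome_kind %in% .outcome_kinds),
       "outcome_kind must be 'continuous' or 'binary'")
  note(!(trials$direction %in% .directions),
       "direction must be 'benefit' or 'harm'")
  note(!(trials$declared_measure %in% .measures),
       paste0("declared_measure must be one of ", paste(.measures, collapse = "/")))
  note(!is.finite(trials$pub_year) | trials$pub_year < 1900 | trials$pub_year > 2100,
       "pub_year outside [1900, 2100]")
  note(!is.finite(trials$active_n) | trials$active_n < 1 |
         !is.finite(trials$placebo_n) | trials$placebo_n < 1,
       "arm sizes must be positive")

  cont <- trials$outcome_kind == "continuous"
  bin <- trials$outcome_kind == "binary"
  has <- function(x) !is.na(x)

  cont_cols <- cbind(trials$active_mean, trials$active_sd,
                     trials$placebo_mean, trials$placebo_sd)
  bin_cols <- cbind(trials$active_events, trials$placebo_events)
  note(cont & rowSums(!is.na(cont_cols)) < 4L,
       "continuous outcome requires active/placebo mean and sd")
  note(cont & rowSums(!is.na(bin_cols)) > 0L,
       "continuous outcome must not carry event counts")
  note(cont & (has(trials$active_sd) & trials$active_sd <= 0),
       "active arm sd must be > 0")
  note(cont & (has(trials$placebo_sd) & trials$placebo_sd <= 0),
       "placebo arm sd must be > 0")
  note(cont & (trials$active_n < 2 | trials$placebo_n < 2),
       "continuous outcome requires n >= 2 per arm")
  note(bin & rowSums(!is.na(bin_cols)) < 2L,
       "binary outcome requires active/placebo event counts")
  note(bin & rowSums(!is.na(cont_cols)) > 0L,
       "binary outcome must not carry means/sds")
  note(bin & has(trials$active_events) &
         (trials$active_events < 0 | trials$active_events > trials$active_n),
       "active events outside [0, active_n]")
  note(bin & has(trials$placebo_events) &
         (trials$placebo_events < 0 | trials$placebo_events > trials$placebo_n),
       "placebo events outside [0, placebo_n]")

  bad <- reasons != ""
  list(
    valid = trials[!bad, , drop = FALSE],
    rejected = data.frame(
      row = which(bad),
      review_id = trials$review_id[bad],
      trial_id = trials$trial_id[bad],
      reason = reasons[bad],
      stringsAsFactors = FALSE
    )
  )
}

#' Raw arm responses
#'
#' Returns the placebo and active arm responses on the raw outcome scale:
#' the arm means for continuous outcomes and the arm event proportions for
#' binary outcomes. No benefit/harm flip is applied; these are the raw
#' quantities whose time trends are examined separately from the effect
#' size.
#'
#' @param trials Trial-level data frame (one or more rows).
#' @return Data frame with columns \code{placebo_response} and
#'   \code{active_response}, one row per trial.
#' @export
arm_responses <- function(trials) {
  cont <- trials$outcome_kind == "continuous"
  placebo <- ifelse(cont, trials$placebo_mean,
                    trials$placebo_events / trials$placebo_n)
  active <- ifelse(cont, trials$active_mean,
                   trials$active_events / trials$active_n)
  data.frame(placebo_response = placebo, active_response = active)
}
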
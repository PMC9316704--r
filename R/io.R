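#' Read a trial-level corpus from CSV
#'
#' Reads a UTF-8, comma-delimited, headered file with one row per trial
#' (see [trial_columns] for the schema), validates every row against the
#' corpus invariants, and returns the valid rows grouped by review in file
#' order. Invalid rows are skipped and reported, never silently coerced.
#'
#' @param path Path to the CSV file.
#' @return List with \code{trials} (validated data frame), \code{rejected}
#'   (data frame of skipped rows with reasons), \code{n_reviews}.
#' @export
read_trials_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  v <- validate_trials(raw)
  if (nrow(v$rejected) > 0L) {
    message(nrow(v$rejected), " row(s) rejected during validation")
  }
  list(trials = v$valid, rejected = v$rejected,
       n_reviews = length(unique(v$valid$review_id)))
}

#' Write a trial-level corpus to CSV
#'
#' Writes the corpus in the schema [read_trials_csv()] reads, so a write /
#' read round trip reproduces the corpus. For a simulated corpus
#' (\code{sim_corpus}), the latent ground truth is written alongside as a
#' tab-delimited sidecar \code{<path>.truth.tsv}.
#'
#' @param x A trial-level data frame or a \code{sim_corpus}.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_corpus <- function(x, path) {
  truth <- NULL
  if (inherits(x, "sim_corpus")) {
    truth <- x$truth$trials
    x <- x$trials
  }
  utils::write.csv(x[, trial_columns], path, row.names = FALSE, na = "")
  if (!is.null(truth)) {
    utils::write.table(truth, paste0(path, ".truth.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Pipeline configuration
#'
#' Settings for [run_pipeline()]: pooling model, small-sample correction,
#' stepwise thresholds, per-review correlation minimum, eligibility rule,
#' and seed. The eligibility defaults (at least 4 trials, at least 3
#' historical) reduce the chance of extreme single-trial results driving
#' the regression.
#'
#' @param method Pooling model, \code{"random_dl"} or \code{"fixed"}.
#' @param hedges Small-sample correction for continuous SMDs.
#' @param enter,remove Stepwise entry/removal p thresholds,
#'   \code{0 < enter < remove < 1}.
#' @param min_trials_trend Minimum trials for a per-review correlation.
#' @param ci_level Confidence level, in (0, 1); informational (the
#'   computation layer uses 95\%).
#' @param seed Seed recorded in the run manifest.
#' @return A list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(method = c("random_dl", "fixed"),
                            hedges = TRUE,
                            enter = 0.05, remove = 0.10,
                            min_trials_trend = 3L,
                            ci_level = 0.95,
                            seed = 1L) {
  method <- match.arg(method)
  if (!(enter > 0 && enter < remove && remove < 1)) {
    stop("thresholds must satisfy 0 < enter < remove < 1")
  }
  if (ci_level <= 0 || ci_level >= 1) stop("ci_level must be in (0, 1)")
  structure(list(method = method, hedges = hedges, enter = enter,
                 remove = remove, min_trials_trend = min_trials_trend,
                 ci_level = ci_level, seed = seed),
            class = "pipeline_config")
}

#' Read a pipeline configuration from JSON
#'
#' Flat key-value JSON mirroring [pipeline_config()]; absent keys take
#' their documented defaults.
#'
#' @param path Path to a JSON file.
#' @return A \code{pipeline_config}.
#' @export
read_pipeline_config <- function(path) {
  keys <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(keys), known)
  if (length(bad) > 0L) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(pipeline_config, keys)
}

#' Run the full constancy pipeline
#'
#' Executes the stages in order on an in-memory corpus: per-trial effect
#' sizes, recency splits, per-review and aggregate time trends, and the
#' weighted stepwise constancy regression over the eligible reviews. The
#' input corpus is never modified. When \code{output_dir} is given, the
#' splits table, per-review trend table, six-category count table,
#' coefficient table and a run manifest (config echo, seed, counts) are
#' written there as delimited text.
#'
#' @param trials Trial-level corpus data frame (already validated; use
#'   [read_trials_csv()] for files).
#' @param config A [pipeline_config()].
#' @param output_dir Optional directory for the output tables.
#' @return A list of class \code{constancy_run}: \code{splits},
#'   \code{splits_table}, \code{trends}, \code{trend_report}, \code{fit},
#'   \code{summary} (corpus descriptives), \code{excluded} (ineligible
#'   review ids), \code{same_year} (reviews excluded from splitting),
#'   \code{manifest}.
#' @export
run_pipeline <- function(trials, config = pipeline_config(),
                         output_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  sp <- split_corpus(trials, method = config$method, hedges = config$hedges)
  rr <- regression_rows(sp)
  if (is.null(rr$rows) || nrow(rr$rows) < 4L) {
    stop("fewer than 4 eligible reviews after filtering (",
         length(sp$splits), " split, ", length(rr$excluded),
         " ineligible, ", length(sp$same_year), " same-year)")
  }
  tr <- corpus_trends(trials, hedges = config$hedges,
                      min_trials = config$min_trials_trend)
  report <- aggregate_trends(tr$trends)
  fit <- stepwise_select(rr$rows, enter = config$enter, remove = config$remove)

  manifest <- list(
    config = unclass(config),
    n_reviews_input = length(unique(trials$review_id)),
    n_trials_input = nrow(trials),
    n_splits = length(sp$splits),
    n_same_year = length(sp$same_year),
    n_eligible = nrow(rr$rows),
    n_ineligible = length(rr$excluded),
    n_trend_reviews = nrow(tr$trends),
    selected_covariates = fit$selected,
    package_version = as.character(utils::packageVersion("constancer"))
  )

  run <- structure(list(
    splits = sp,
    splits_table = splits_table(sp),
    trends = tr$trends,
    trend_report = report,
    fit = fit,
    summary = corpus_summary(sp),
    excluded = rr$excluded,
    same_year = sp$same_year,
    manifest = manifest
  ), class = "constancy_run")

  if (!is.null(output_dir)) write_run(run, output_dir)
  run
}

#' Write a pipeline run's tables
#'
#' Emits the delimited-text outputs of a [run_pipeline()] result:
#' \code{splits.tsv}, \code{trends.tsv}, \code{trend_categories.tsv}
#' (six-category counts for SMD / placebo / active),
#' \code{coefficients.tsv} (term, B, 95\% CI, p) and \code{manifest.json}.
#'
#' @param run A \code{constancy_run}.
#' @param output_dir Directory, created if needed.
#' @return \code{output_dir}, invisibly.
#' @export
write_run <- function(run, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(d, f) {
    utils::write.table(d, file.path(output_dir, f), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  wt(run$splits_table, "splits.tsv")
  trends_out <- run$trends
  for (v in grep("^category_", names(trends_out), value = TRUE)) {
    trends_out[[v]] <- as.character(trends_out[[v]])
  }
  wt(trends_out, "trends.tsv")
  cats <- as.data.frame(run$trend_report$categories)
  cats <- cbind(category = rownames(cats), cats)
  wt(cats, "trend_categories.tsv")
  coefs <- run$fit$coefficients
  coefs$estimate <- signif(coefs$estimate, 10)
  wt(coefs, "coefficients.tsv")
  jsonlite::write_json(run$manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(output_dir)
}

#' @export
print.constancy_run <- function(x, ...) {
  print(x$summary)
  cat("\n")
  print(x$trend_report)
  cat("\n")
  print(x$fit)
  invisible(x)
}
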
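#' Assemble a run configuration
#'
#' A run either simulates a cohort (`simulate` block, a [cohort_config()]
#' or a list of its arguments) or loads existing tables (`inputs`, a named
#' list of file paths) — exactly one of the two. Thresholds, the window
#' grid and the analysis arms are configurable; everything can be given in
#' one YAML file.
#'
#' @param simulate Optional [cohort_config()] or argument list.
#' @param inputs Optional named list of paths (`prompts`, `recall`,
#'   `epochs`, optionally `participants`).
#' @param thresholds A [filter_thresholds()] or argument list.
#' @param arm One of `"both"`, `"diet"`, `"pa"`.
#' @param grid Window half-width grid (minutes).
#' @param out_dir Output directory.
#' @param seed Integer seed (overrides the simulate block's seed).
#' @return Object of class `run_config`.
#' @export
run_config <- function(simulate = NULL, inputs = NULL,
                       thresholds = filter_thresholds(),
                       arm = c("both", "diet", "pa"),
                       grid = seq(6, 480, by = 6),
                       out_dir = "emavalid-report", seed = 1L) {
  if (is.null(simulate) == is.null(inputs)) {
    stop("exactly one of `simulate` and `inputs` must be given", call. = FALSE)
  }
  if (!is.null(simulate) && !inherits(simulate, "cohort_config")) {
    simulate <- do.call(cohort_config, simulate)
  }
  if (!inherits(thresholds, "filter_thresholds")) {
    thresholds <- do.call(filter_thresholds, as.list(thresholds))
  }
  if (!is.null(simulate)) simulate$seed <- as.integer(seed)
  structure(list(simulate = simulate, inputs = inputs,
                 thresholds = thresholds, arm = match.arg(arm),
                 grid = grid, out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file with optional blocks `simulate`, `inputs`,
#'   `thresholds` and scalar fields `arm`, `out_dir`, `seed`, `grid`
#'   (list of `from`, `to`, `by`).
#' @param ... Overrides passed to [run_config()].
#' @return A `run_config`.
#' @export
read_run_config <- function(path, ...) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$simulate)) {
    for (nm in c("time_blocks", "misreport_matrix")) {
      if (!is.null(y$simulate[[nm]])) {
        y$simulate[[nm]] <- do.call(rbind, y$simulate[[nm]])
      }
    }
    for (nm in c("food_group_probs", "pa_level_probs", "recall_days_range",
                 "day_kcal_range", "latency_range")) {
      if (!is.null(y$simulate[[nm]])) {
        y$simulate[[nm]] <- unlist(y$simulate[[nm]])
      }
    }
  }
  args <- list(simulate = y$simulate, inputs = y$inputs)
  if (!is.null(y$thresholds)) args$thresholds <- y$thresholds
  if (!is.null(y$arm)) args$arm <- y$arm
  if (!is.null(y$out_dir)) args$out_dir <- y$out_dir
  if (!is.null(y$seed)) args$seed <- y$seed
  if (!is.null(y$grid)) args$grid <- seq(y$grid$from, y$grid$to, by = y$grid$by)
  args <- utils::modifyList(args, list(...))
  do.call(run_config, args)
}

#' Run the full validation report
#'
#' Ties simulation (or loading), ingest filtering and both analysis arms
#' into one deterministic run. Every emitted table is written as delimited
#' text under the output directory, together with the exclusion ledgers, a
#' plain-text provenance log, a YAML run manifest and one machine-readable
#' JSON summary. A failure in one arm is recorded in the summary and log
#' while the other arm still completes; the returned object's
#' `any_failed` field (and the CLI exit status) reflects it.
#'
#' @param config A [run_config()] (or path to a YAML file).
#' @param write Write output files (default `TRUE`; `FALSE` returns the
#'   result bundle only).
#' @return Object of class `validation_report`: list with `diet`
#'   (`diet_validation` or `NULL`), `pa` (`pa_validation` or `NULL`),
#'   `summary` (list serialised to JSON), `log`, `files`, `any_failed`.
#' @export
run_validation_report <- function(config, write = TRUE) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  log <- character(0)
  files <- character(0)

  if (!is.null(config$simulate)) {
    log <- log_line(log, "INFO", paste("simulating cohort, seed",
                                       config$simulate$seed))
    bundle <- generate_cohort(config$simulate)
    study <- bundle[c("prompts", "recall", "epochs", "participants")]
  } else {
    log <- log_line(log, "INFO", "loading study tables")
    study <- load_study(config$inputs)
    log <- c(log, study$log)
  }

  out <- list(diet = NULL, pa = NULL)
  errors <- list()
  if (config$arm %in% c("both", "diet")) {
    out$diet <- tryCatch(
      validate_diet(study$prompts, study$recall, study$participants,
                    config$thresholds, config$grid),
      error = function(e) { errors$diet <<- conditionMessage(e); NULL })
    log <- log_line(log, if (is.null(out$diet)) "ERROR" else "INFO",
                    if (is.null(out$diet))
                      paste("diet arm failed:", errors$diet) else
                        sprintf("diet arm: %d analyzed days [day_match_rates, window_match_curve, window_sens_spec, subgroup_chisq, diet_mixed_logit]",
                                nrow(out$diet$days)))
  }
  if (config$arm %in% c("both", "pa")) {
    out$pa <- tryCatch(
      validate_pa(study$prompts, study$epochs, config$thresholds),
      error = function(e) { errors$pa <<- conditionMessage(e); NULL })
    log <- log_line(log, if (is.null(out$pa)) "ERROR" else "INFO",
                    if (is.null(out$pa))
                      paste("pa arm failed:", errors$pa) else
                        sprintf("pa arm: %d occasions [pa_occasions, crosstab_and_agreement, pa_or_mixed_logit, ks_pairwise, logcount_mixed_lm]",
                                nrow(out$pa$occasions)))
  }

  summary <- list(seed = config$seed, arm = config$arm,
                  failed = names(errors), errors = errors)
  if (!is.null(out$diet)) {
    summary$diet <- list(
      n_days = nrow(out$diet$days),
      n_excluded_days = nrow(out$diet$exclusions),
      day_match = out$diet$day_match$summary,
      mixed_logit = out$diet$mixed_logit)
  }
  if (!is.null(out$pa)) {
    summary$pa <- list(
      n_occasions = nrow(out$pa$occasions),
      n_excluded = nrow(out$pa$exclusions),
      crosstab = unname(apply(out$pa$crosstab$crosstab, 1, as.integer,
                              simplify = FALSE)),
      agreement = out$pa$crosstab$agreement,
      or_mixed = out$pa$or_mixed, ks = out$pa$ks,
      logcount_contrasts = out$pa$logcount$contrasts)
  }

  if (write) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    wcsv <- function(df, name) {
      p <- file.path(config$out_dir, name)
      for (col in names(df)) {
        if (inherits(df[[col]], "POSIXct")) df[[col]] <- format_ts(df[[col]])
      }
      utils::write.csv(df, p, row.names = FALSE, na = "")
      files <<- c(files, p)
    }
    if (!is.null(out$diet)) {
      wcsv(round_report(out$diet$day_match$summary,
                        c(match_rate = 1)), "diet_day_match.csv")
      wcsv(round_report(out$diet$window_curve, c(ppv = 1)), "diet_window_curve.csv")
      wcsv(round_report(out$diet$window_sens_spec,
                        c(sensitivity = 0, specificity = 0)),
           "diet_window_sens_spec.csv")
      wcsv(round_report(out$diet$mixed_logit,
                        c(or = 2, ci_lo = 2, ci_hi = 2)), "diet_mixed_logit.csv")
      wcsv(out$diet$exclusions, "diet_exclusions.csv")
      if (!is.null(out$diet$chisq)) {
        for (nm in names(out$diet$chisq)) {
          wcsv(out$diet$chisq[[nm]], paste0("diet_chisq_", nm, ".csv"))
        }
      }
    }
    if (!is.null(out$pa)) {
      ct <- as.data.frame(out$pa$crosstab$crosstab)
      wcsv(data.frame(reported = rownames(out$pa$crosstab$crosstab),
                      out$pa$crosstab$crosstab, check.names = FALSE),
           "pa_crosstab.csv")
      wcsv(round_report(out$pa$crosstab$agreement,
                        c(match_rate = 1, sensitivity = 0, specificity = 0,
                          lr_plus = 2, lr_minus = 2)), "pa_agreement.csv")
      wcsv(round_report(out$pa$or_mixed, c(or = 2, ci_lo = 2, ci_hi = 2)),
           "pa_or_mixed.csv")
      wcsv(out$pa$ks, "pa_ks.csv")
      wcsv(out$pa$logcount$contrasts, "pa_logcount_contrasts.csv")
      wcsv(out$pa$participant_means$inversions, "pa_participant_inversions.csv")
      wcsv(out$pa$exclusions, "pa_exclusions.csv")
    }
    manifest <- list(seed = config$seed, arm = config$arm,
                     thresholds = unclass(config$thresholds),
                     grid = list(from = min(config$grid), to = max(config$grid),
                                 by = if (length(config$grid) > 1)
                                   diff(config$grid)[1] else NA),
                     simulated = !is.null(config$simulate))
    yaml::write_yaml(manifest, file.path(config$out_dir, "run_manifest.yaml"))
    jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = 10, dataframe = "rows",
                         na = "null", pretty = TRUE)
    writeLines(log, file.path(config$out_dir, "run.log"))
    files <- c(files, file.path(config$out_dir,
                                c("run_manifest.yaml", "summary.json", "run.log")))
  }

  structure(list(diet = out$diet, pa = out$pa, summary = summary, log = log,
                 files = files, any_failed = length(errors) > 0),
            class = "validation_report")
}

# reporting-layer rounding: full precision is retained in the objects;
# only written tables are rounded to the conventional printed precision
round_report <- function(df, digits) {
  for (nm in names(digits)) {
    if (nm %in% names(df)) df[[nm]] <- round(df[[nm]], digits[[nm]])
  }
  df
}

#' @export
print.validation_report <- function(x, ...) {
  cat("EMA validation report\n")
  if (!is.null(x$diet)) print(x$diet)
  if (!is.null(x$pa)) print(x$pa)
  if (x$any_failed) cat("NOTE: some arm(s) failed:",
                        paste(x$summary$failed, collapse = ", "), "\n")
  invisible(x)
}
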
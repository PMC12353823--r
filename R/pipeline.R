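# Pipeline orchestration: CSV schemas, end-to-end analysis, run log.
#
# CSV conventions: one header row, UTF-8, missing values as empty fields;
# dates as ISO-8601. participants.csv / visits.csv / nsaa_items.csv /
# fibers.csv / lcms.csv are the interchange schemas of the synthetic-data
# module and of apply_eligibility/endpoint_battery inputs.

study_files <- c(participants = "participants.csv", visits = "visits.csv",
                 nsaa_items = "nsaa_items.csv", fibers = "fibers.csv",
                 lcms = "lcms.csv")

#' Write a study to CSV files
#'
#' @param study A `simulated_study` (or compatible list of data frames).
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_study_csv <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (nm in names(study_files)) {
    if (is.null(study[[nm]])) next
    path <- file.path(dir, study_files[[nm]])
    write.csv(study[[nm]], path, row.names = FALSE, na = "",
              fileEncoding = "UTF-8")
    paths <- c(paths, path)
  }
  if (!is.null(study$truth) &&
      requireNamespace("jsonlite", quietly = TRUE)) {
    truth <- study$truth
    truth$config <- unclass(truth$config)
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    paths <- c(paths, file.path(dir, "truth.json"))
  }
  invisible(paths)
}

#' Read a study back from CSV files
#'
#' @param dir Directory containing the study CSV files.
#' @return A `simulated_study`-shaped list (without `truth`).
#' @export
read_study_csv <- function(dir) {
  out <- list()
  for (nm in names(study_files)) {
    path <- file.path(dir, study_files[[nm]])
    if (!file.exists(path)) next
    d <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
    for (col in intersect(c("steroid_start", "screening_date"), names(d)))
      d[[col]] <- as.Date(d[[col]])
    out[[nm]] <- d
  }
  if (!length(out)) stop("no study files found in ", dir, call. = FALSE)
  structure(out, class = "simulated_study")
}

config_fingerprint <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(x), f)
  unname(tools::md5sum(f))
}

#' Run the full external-control analysis pipeline
#'
#' Executes, in order: steroid-date imputation and eligibility selection of
#' the external cohort; propensity fitting, ATT weighting with trimming;
#' covariate balance diagnostics; the endpoint effect battery with
#' bootstrap inference; age-stratified NSAA changes; item-level skill
#' summaries; and (when fiber/LC-MS tables are present) dystrophin
#' expression quantification. Any stage error aborts with the stage name;
#' stages completed so far are retained in the partial result.
#'
#' @param study A study list (see [generate_study()] / [read_study_csv()]).
#' @param seed Integer seed for the bootstrap streams.
#' @param B Bootstrap replicates per endpoint (default 2000).
#' @param trim_quantile Weight trimming quantile (default 0.95).
#' @param estimator `"iptw"` (default) or `"aipw"`.
#' @param out_dir Optional directory; when given, result tables are written
#'   as CSV files along with a plain-text run log.
#' @param verbose Print stage progress (default `FALSE`).
#' @return A list of class `pipeline_report`: `selection`, `weights`,
#'   `balance`, `battery`, `age_strata`, `skills`, `dystrophin`, `log`.
#' @export
run_pipeline <- function(study, seed, B = 2000L, trim_quantile = 0.95,
                         estimator = c("iptw", "aipw"), out_dir = NULL,
                         verbose = FALSE) {
  estimator <- match.arg(estimator)
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  t0 <- Sys.time()
  fingerprint <- config_fingerprint(list(seed = seed, B = B,
                                         trim_quantile = trim_quantile,
                                         estimator = estimator))
  log <- data.frame(stage = character(), rows = integer(),
                    elapsed_s = numeric(), stringsAsFactors = FALSE)
  note <- function(stage, rows) {
    log <<- rbind(log, data.frame(
      stage = stage, rows = rows,
      elapsed_s = round(as.numeric(Sys.time() - t0, units = "secs"), 2)))
    if (verbose) message(sprintf("[%s] %s (%d rows)",
                                 format(Sys.time(), "%H:%M:%S"), stage, rows))
  }
  result <- list(config = list(seed = seed, B = B,
                               trim_quantile = trim_quantile,
                               estimator = estimator,
                               fingerprint = fingerprint))
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  result$selection <- run_stage("selection", {
    p <- impute_steroid_start(study$participants)
    apply_eligibility(p, study$nsaa_items)
  })
  cohort <- result$selection$cohort
  note("selection", nrow(cohort))

  result$weights <- run_stage("weighting", {
    trim_and_renormalize(att_weights(fit_propensity(cohort)),
                         trim_quantile)
  })
  note("weighting", nrow(result$weights))

  result$balance <- run_stage("balance",
                              balance_table(cohort, result$weights))
  note("balance", nrow(result$balance))

  result$battery <- run_stage("battery",
    endpoint_battery(cohort, study$visits, B = B, seed = seed,
                     estimator = estimator, trim_quantile = trim_quantile))
  note("battery", nrow(result$battery))

  result$age_strata <- run_stage("age_strata",
    age_stratified_changes(cohort, study$visits, result$weights))
  note("age_strata", nrow(result$age_strata))

  result$skills <- run_stage("skills", {
    items <- study$nsaa_items[study$nsaa_items$id %in% cohort$id, ,
                              drop = FALSE]
    skill_summary(items)
  })
  note("skills", nrow(result$skills$by_arm))

  if (!is.null(study$fibers) && nrow(study$fibers) > 0) {
    result$dystrophin <- run_stage("dystrophin", {
      thr <- fit_threshold(study$fibers)
      quant <- average_sections(pct_positive(study$fibers, thr))
      expr_fibers <- expression_summary(quant)
      lc <- NULL
      if (!is.null(study$lcms) && nrow(study$lcms) > 0) {
        lp <- study$truth$config$lcms_params %||%
          list(control_mean = 2964, lloq = 10)
        pn <- lcms_percent_normal(study$lcms$conc, lp$control_mean, lp$lloq)
        lc <- cbind(study$lcms[c("id", "visit")], pn)
      }
      list(threshold = thr, biopsy_quant = quant,
           expression_fibers = expr_fibers,
           lcms = lc,
           expression_lcms = if (!is.null(lc))
             expression_summary(lc, "pct_normal"))
    })
    note("dystrophin", nrow(result$dystrophin$biopsy_quant))
  } else {
    warning("no fiber table present; dystrophin stages skipped")
    note("dystrophin (skipped)", 0L)
  }

  result$log <- log
  class(result) <- "pipeline_report"
  if (!is.null(out_dir)) write_report(result, out_dir)
  result
}

write_report <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(d, f) write.csv(d, file.path(out_dir, f),
                                   row.names = FALSE, na = "",
                                   fileEncoding = "UTF-8")
  wcsv(result$selection$flags, "selection_report.csv")
  wcsv(result$selection$cohort, "cohort.csv")
  w <- result$weights
  wcsv(data.frame(id = w$id, arm = w$arm, p = w$p, w_final = w$w),
       "weights.csv")
  wcsv(as.data.frame(result$balance), "balance.csv")
  wcsv(as.data.frame(result$battery), "effects.csv")
  wcsv(result$age_strata, "age_strata.csv")
  wcsv(result$skills$by_arm, "skill_summary.csv")
  wcsv(result$skills$per_participant, "skills.csv")
  if (!is.null(result$dystrophin)) {
    wcsv(result$dystrophin$biopsy_quant, "biopsy_quant.csv")
    wcsv(result$dystrophin$expression_fibers, "expression_summary.csv")
  }
  lines <- c(sprintf("run fingerprint: %s", result$config$fingerprint),
             sprintf("seed=%d B=%d trim=%.3f estimator=%s",
                     result$config$seed, result$config$B,
                     result$config$trim_quantile, result$config$estimator),
             apply(result$log, 1L, paste, collapse = " | "))
  writeLines(lines, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  cat(sprintf("  cohort: %d participants (%d external selected of %d)\n",
              nrow(x$selection$cohort), x$selection$n_selected,
              x$selection$n_in))
  cat(sprintf("  max weighted |SMD|: %.3f\n",
              attr(x$balance, "max_abs")[["weighted"]]))
  cat("  endpoint battery:\n")
  b <- as.data.frame(x$battery)
  print.data.frame(b[c("endpoint", "ls_mean_treated", "ls_mean_external",
                       "difference", "se_boot", "ci_low", "ci_high",
                       "p_one_sided")],
                   row.names = FALSE, digits = 3)
  invisible(x)
}
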
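# External-control cohort derivation: eligibility rules and imputation.

#' Impute missing steroid-regimen start dates
#'
#' A missing steroid start date is imputed as 6 calendar months before the
#' screening day (day-of-month clamped at month ends); present values are
#' left untouched. An `steroid_imputed` flag column records which rows were
#' filled in.
#'
#' @param records Data frame of participant records with columns
#'   `steroid_start` and `screening_date` (`Date` or ISO-8601 strings).
#' @return `records` with `steroid_start` completed and a logical
#'   `steroid_imputed` column appended.
#' @examples
#' rec <- data.frame(steroid_start = as.Date(NA),
#'                   screening_date = as.Date("2020-07-01"))
#' impute_steroid_start(rec)
#' @export
impute_steroid_start <- function(records) {
  records$steroid_start <- as.Date(records$steroid_start)
  records$screening_date <- as.Date(records$screening_date)
  miss <- is.na(records$steroid_start)
  if (any(miss & is.na(records$screening_date)))
    stop("cannot impute steroid start: screening_date missing for id(s) ",
         paste(records$id[miss & is.na(records$screening_date)],
               collapse = ", "), call. = FALSE)
  if (any(miss))
    records$steroid_start[miss] <- add_months(records$screening_date[miss], -6L)
  records$steroid_imputed <- miss
  records
}

#' Ambulation rule from NSAA item scores
#'
#' A participant is ambulatory when NSAA item 17 (10-m run/walk) scores 1 or
#' 2; if item 17 is missing, a score of 1 or 2 on item 2 (walk) rescues the
#' participant. The published rule also contains a disjunct under which any
#' observed item-17 score (including 0) qualifies; read literally it makes
#' the first disjunct redundant, so the charitable reading above is the
#' default and `literal = TRUE` restores the printed text.
#'
#' @param items Either a numeric vector of 17 item scores (0/1/2 or `NA`) or
#'   a data frame / matrix with item columns (`item01` ... `item17`), one row
#'   per participant.
#' @param literal Use the literal printed rule (any non-missing item 17
#'   qualifies)? Default `FALSE`.
#' @return Logical vector, one element per participant.
#' @examples
#' is_ambulatory_by_nsaa(c(rep(2, 16), 0))
#' @export
is_ambulatory_by_nsaa <- function(items, literal = FALSE) {
  m <- item_matrix(items)
  i17 <- m[, 17L]
  i2 <- m[, 2L]
  if (any(apply(m, 1L, function(r) all(is.na(r)))))
    warning("participant(s) with all item scores missing treated as ",
            "non-ambulatory")
  ok <- (!is.na(i17) & i17 %in% c(1, 2)) |
    (is.na(i17) & !is.na(i2) & i2 %in% c(1, 2))
  if (literal) ok <- ok | (!is.na(i17) & i17 == 0)
  unname(ok)
}

item_matrix <- function(items) {
  if (is.data.frame(items) || is.matrix(items)) {
    cols <- grep("^item[0-9]{2}$", colnames(items), value = TRUE)
    if (length(cols) == 17L) items <- items[, cols]
    m <- as.matrix(items)
  } else {
    m <- matrix(as.numeric(items), nrow = 1L)
  }
  if (ncol(m) != 17L)
    stop("expected 17 NSAA item scores, got ", ncol(m), call. = FALSE)
  storage.mode(m) <- "numeric"
  m
}

#' Apply external-control eligibility criteria
#'
#' Retains pool participants satisfying all of: age 4-12 years at screening
#' (inclusive); ambulatory per [is_ambulatory_by_nsaa()]; able to rise from
#' the floor within 7 s (inclusive; the velocity encoding `>= 1/7` per
#' second is used when no time is recorded); LVEF at least 55% when LVEF is
#' available ("data permitting" -- a missing LVEF does not exclude); a
#' stable steroid regimen for at least 6 months at screening; and
#' non-missing NSAA total scores at both baseline and 1 year. Treated-arm
#' rows pass through unscreened (they entered the trial through its own
#' eligibility process).
#'
#' @param participants Data frame of participant records (see
#'   [generate_study()] for the schema); steroid imputation via
#'   [impute_steroid_start()] should already have been applied.
#' @param nsaa_items Item-score data frame with a `visit` column; the
#'   baseline rows drive the ambulation rule. Optional -- when absent the
#'   ambulation rule falls back to `run10_velocity > 0`.
#' @param lvef_inclusive Treat LVEF exactly 55% as passing (default `TRUE`;
#'   the source texts disagree between "greater than 55%" and ">= 55%").
#' @param literal_ambulation Passed to [is_ambulatory_by_nsaa()].
#' @return A list of class `selection_report` with elements `cohort` (the
#'   retained rows), `flags` (per-participant per-rule pass indicators),
#'   `n_in`, `n_selected`, and `exclusions` (per-rule failure tally among
#'   pool participants).
#' @examples
#' study <- generate_study(sim_config(seed = 1, n_treated = 4, n_pool = 30))
#' sel <- apply_eligibility(study$participants, study$nsaa_items)
#' sel$n_selected
#' @export
apply_eligibility <- function(participants, nsaa_items = NULL,
                              lvef_inclusive = TRUE,
                              literal_ambulation = FALSE) {
  if (nrow(participants) == 0L) stop("empty pool", call. = FALSE)
  p <- participants
  if (!"steroid_imputed" %in% names(p)) p <- impute_steroid_start(p)

  age_ok <- !is.na(p$age_screening) &
    p$age_screening >= 4 & p$age_screening <= 12

  if (!is.null(nsaa_items)) {
    base <- nsaa_items[nsaa_items$visit == "baseline", , drop = FALSE]
    amb <- is_ambulatory_by_nsaa(base[match(p$id, base$id), , drop = FALSE],
                                 literal = literal_ambulation)
    amb[is.na(amb)] <- FALSE
  } else {
    amb <- !is.na(p$run10_velocity) & p$run10_velocity > 0
  }

  rise_ok <- ifelse(!is.na(p$rise_time), p$rise_time <= 7,
                    !is.na(p$rise_velocity) & p$rise_velocity >= 1 / 7)

  lvef_ok <- is.na(p$lvef) |  # "data permitting": missing LVEF retained
    (if (lvef_inclusive) p$lvef >= 55 else p$lvef > 55)

  months_ster <- months_between(p$steroid_start, p$screening_date)
  steroid_ok <- !is.na(months_ster) & months_ster >= 6

  nsaa_base_ok <- !is.na(p$nsaa_total_baseline)
  nsaa_yr1_ok <- !is.na(p$nsaa_total_year1)

  flags <- data.frame(
    id = p$id,
    age = age_ok, ambulatory = amb, rise = rise_ok, lvef = lvef_ok,
    steroid = steroid_ok, nsaa_baseline = nsaa_base_ok,
    nsaa_year1 = nsaa_yr1_ok,
    stringsAsFactors = FALSE
  )
  rules <- setdiff(names(flags), "id")
  pass <- rowSums(!flags[rules]) == 0L
  treated <- is_treated_arm(p$arm)
  keep <- treated | pass

  pool_flags <- flags[!treated, , drop = FALSE]
  exclusions <- vapply(rules, function(r) sum(!pool_flags[[r]]), integer(1))

  structure(list(
    cohort = p[keep, , drop = FALSE],
    flags = flags,
    n_in = sum(!treated),
    n_selected = sum(pass & !treated),
    exclusions = exclusions
  ), class = "selection_report")
}

months_between <- function(from, to) {
  from <- as.Date(from); to <- as.Date(to)
  lf <- as.POSIXlt(from); lt <- as.POSIXlt(to)
  m <- (lt$year - lf$year) * 12L + (lt$mon - lf$mon)
  # incomplete final month does not count
  m - ifelse(lt$mday < lf$mday, 1L, 0L)
}

#' @export
print.selection_report <- function(x, ...) {
  cat("<selection_report>\n")
  cat(sprintf("  pool screened: %d | selected: %d\n", x$n_in, x$n_selected))
  cat("  exclusions by rule (pool, non-exclusive):\n")
  for (r in names(x$exclusions))
    cat(sprintf("    %-14s %d\n", r, x$exclusions[[r]]))
  invisible(x)
}
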
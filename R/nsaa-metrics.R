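# Item-level NSAA analytics: totals, skills gained / improved-or-maintained.

#' NSAA total score from item scores
#'
#' Sums the 17 item scores (each 0, 1 or 2) over non-missing items; the
#' number of missing items is reported alongside.
#'
#' @param items Numeric vector of up to 17 item scores (0/1/2 or `NA`), or
#'   a one-row item data frame.
#' @return A list with `total` (integer) and `missing_count`.
#' @examples
#' nsaa_total(rep(2, 17))$total  # 34
#' @export
nsaa_total <- function(items) {
  x <- as.numeric(item_scores(items))
  bad <- !is.na(x) & !x %in% c(0, 1, 2)
  if (any(bad))
    stop("item scores must be 0, 1 or 2 (got ",
         paste(unique(x[bad]), collapse = ", "), ")", call. = FALSE)
  list(total = as.integer(sum(x, na.rm = TRUE)),
       missing_count = sum(is.na(x)))
}

item_scores <- function(items) {
  if (is.data.frame(items) || is.matrix(items)) {
    m <- item_matrix(items)
    if (nrow(m) != 1L) stop("expected a single item vector", call. = FALSE)
    drop(m)
  } else {
    if (length(items) > 17L)
      stop("expected at most 17 item scores", call. = FALSE)
    items
  }
}

#' Count skills gained between baseline and 1 year
#'
#' A skill is gained when an item that could not be performed at baseline
#' (observed score 0) is performed at 1 year (score 1 or 2). Items missing
#' at either visit are not counted.
#'
#' @param baseline,year1 Item-score vectors for the same participant.
#' @return Integer count of gained skills.
#' @examples
#' skills_gained(c(0, rep(2, 16)), c(1, rep(2, 16)))  # 1
#' @export
skills_gained <- function(baseline, year1) {
  b <- as.numeric(item_scores(baseline))
  y <- as.numeric(item_scores(year1))
  sum(!is.na(b) & !is.na(y) & b == 0 & y %in% c(1, 2))
}

#' Count skills improved or maintained between baseline and 1 year
#'
#' A skill is improved or maintained when the 1-year score is non-zero and
#' not below the baseline score (`year1 >= max(baseline, 1)`); under this
#' default reading a 0-to-1 transition counts as improved (and also as
#' gained). `strict = TRUE` additionally requires a non-zero baseline.
#' Items missing at either visit are excluded.
#'
#' @param baseline,year1 Item-score vectors for the same participant.
#' @param strict Require baseline > 0 as well? Default `FALSE`.
#' @return Integer count.
#' @examples
#' skills_improved_or_maintained(rep(2, 17), rep(2, 17))  # 17
#' @export
skills_improved_or_maintained <- function(baseline, year1, strict = FALSE) {
  b <- as.numeric(item_scores(baseline))
  y <- as.numeric(item_scores(year1))
  ok <- !is.na(b) & !is.na(y) & y >= pmax(b, 1)
  if (strict) ok <- ok & b >= 1
  sum(ok)
}

#' Per-arm skill summary
#'
#' For each arm: the number of participants with at least one baseline item
#' scored 0, how many of those gained at least one skill (with the
#' percentage over that baseline-zero subset), and the median number of
#' skills improved or maintained over all participants with item data at
#' both visits.
#'
#' @param nsaa_items Item table with columns `id`, `arm`, `visit`
#'   (`"baseline"`/`"year1"`) and `item01` ... `item17`.
#' @param strict Passed to [skills_improved_or_maintained()].
#' @return A list of class `skill_summary`: `by_arm` (one row per arm) and
#'   `per_participant` (id, arm, baseline zeros, gains, improved count).
#' @examples
#' skill_summary(worked_example_fixture()$nsaa_items)
#' @export
skill_summary <- function(nsaa_items, strict = FALSE) {
  base <- nsaa_items[nsaa_items$visit == "baseline", , drop = FALSE]
  yr1 <- nsaa_items[nsaa_items$visit == "year1", , drop = FALSE]
  ids <- intersect(base$id, yr1$id)
  if (!length(ids)) stop("no participants with both visits", call. = FALSE)
  per <- lapply(ids, function(i) {
    b <- item_matrix(base[base$id == i, , drop = FALSE])[1, ]
    y <- item_matrix(yr1[yr1$id == i, , drop = FALSE])[1, ]
    if (all(is.na(y)) || all(is.na(b))) return(NULL)  # missing visit data
    data.frame(
      id = i, arm = base$arm[base$id == i][1],
      n_baseline_zero = sum(!is.na(b) & b == 0),
      n_gained = skills_gained(b, y),
      n_improved_or_maintained = skills_improved_or_maintained(b, y, strict),
      n_item_missing = sum(is.na(b) | is.na(y)),
      stringsAsFactors = FALSE
    )
  })
  per <- do.call(rbind, per)
  by_arm <- do.call(rbind, lapply(split(per, per$arm), function(d) {
    bz <- d$n_baseline_zero > 0
    ng <- sum(bz & d$n_gained > 0)
    data.frame(
      arm = d$arm[1], n = nrow(d),
      n_with_baseline_zero = sum(bz),
      n_gained_ge1 = ng,
      pct_gained = if (sum(bz) > 0) 100 * ng / sum(bz) else NA_real_,
      median_improved_or_maintained = median(d$n_improved_or_maintained),
      stringsAsFactors = FALSE
    )
  }))
  rownames(by_arm) <- NULL
  structure(list(by_arm = by_arm, per_participant = per),
            class = "skill_summary")
}

#' @export
print.skill_summary <- function(x, ...) {
  cat("<skill_summary>\n")
  print.data.frame(x$by_arm, row.names = FALSE, digits = 4)
  invisible(x)
}
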
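# Dystrophin / mini-dystrophin expression quantification:
# fiber-positivity thresholding, two-section averaging, LC-MS
# percent-of-normal normalization.

#' Fit the global fiber-positivity threshold
#'
#' The positivity threshold is the 99th percentile (linear-interpolation
#' quantile) of the mean stain density (MSD) distribution pooled over all
#' baseline fibers from all participants and sections. Any fiber with MSD
#' strictly above this value is subsequently scored positive.
#'
#' @param baseline_fibers Fiber table (`id`, `section`, `fiber`, `msd`, and
#'   optionally `visit`); rows with `visit != "baseline"` are dropped.
#' @return An object of class `threshold_model`: `threshold`, `quantile`
#'   (fixed at 0.99), `source_n_fibers`, `source_n_participants`, and the
#'   quantile convention.
#' @examples
#' fib <- data.frame(id = "T01", section = "A", fiber = 1:1000,
#'                   msd = 1:1000)
#' fit_threshold(fib)$threshold  # 990.01
#' @export
fit_threshold <- function(baseline_fibers) {
  f <- baseline_fibers
  if ("visit" %in% names(f)) f <- f[f$visit == "baseline", , drop = FALSE]
  if (nrow(f) == 0L) stop("no baseline fibers", call. = FALSE)
  if (nrow(f) < 100L)
    warning("threshold fitted on fewer than 100 fibers")
  if (any(f$msd <= 0)) stop("MSD values must be positive", call. = FALSE)
  structure(list(
    threshold = quantile_linear(f$msd, 0.99),
    quantile = 0.99,
    quantile_type = "linear interpolation (type 7)",
    source_n_fibers = nrow(f),
    source_n_participants = length(unique(f$id))
  ), class = "threshold_model")
}

#' @export
print.threshold_model <- function(x, ...) {
  cat(sprintf(
    "<threshold_model> MSD > %.4f (99th percentile of %d baseline fibers, %d participants)\n",
    x$threshold, x$source_n_fibers, x$source_n_participants))
  invisible(x)
}

#' Percent positive fibers per biopsy section
#'
#' Scores each fiber positive when its MSD is strictly above the fitted
#' threshold (ties are negative) and reports the percentage per
#' (participant, visit, section).
#'
#' @param fibers Fiber table.
#' @param model A [fit_threshold()] result (or a bare numeric threshold).
#' @return Data frame: `id`, `visit`, `section`, `n_fibers`,
#'   `pct_positive`.
#' @export
pct_positive <- function(fibers, model) {
  thr <- if (inherits(model, "threshold_model")) model$threshold
  else as.numeric(model)
  if (nrow(fibers) == 0L) stop("empty fiber table", call. = FALSE)
  key <- interaction(fibers$id, fibers$visit, fibers$section, drop = TRUE)
  rows <- lapply(split(fibers, key), function(d) {
    data.frame(id = d$id[1], visit = d$visit[1], section = d$section[1],
               n_fibers = nrow(d),
               pct_positive = 100 * mean(d$msd > thr),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$id, out$visit, out$section), , drop = FALSE]
}

#' Average the two biopsy sections per visit
#'
#' Two sections are analyzed per muscle biopsy; the reported percentage per
#' participant and visit is the arithmetic mean of the two section values.
#' Single-section biopsies pass through with a flag; more than two sections
#' is an error.
#'
#' @param per_section Output of [pct_positive()].
#' @return Data frame: `id`, `visit`, `n_sections`, `pct_positive_mean`,
#'   `single_section` flag.
#' @examples
#' ps <- data.frame(id = "T01", visit = "year1", section = c("A", "B"),
#'                  n_fibers = 100, pct_positive = c(10, 30))
#' average_sections(ps)$pct_positive_mean  # 20
#' @export
average_sections <- function(per_section) {
  key <- interaction(per_section$id, per_section$visit, drop = TRUE)
  rows <- lapply(split(per_section, key), function(d) {
    if (nrow(d) > 2L)
      stop("more than two sections for participant ", d$id[1], " at ",
           d$visit[1], call. = FALSE)
    data.frame(id = d$id[1], visit = d$visit[1],
               n_sections = nrow(d),
               pct_positive_mean = mean(d$pct_positive),
               single_section = nrow(d) == 1L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$id, out$visit), , drop = FALSE]
}

#' LC-MS dystrophin concentration as percent of normal
#'
#' Concentrations below the lower limit of quantification (LLOQ) are
#' imputed as half the LLOQ before normalization; percent of normal is the
#' concentration over the mean of non-dystrophic control tissues, times
#' 100.
#'
#' @param conc Numeric concentrations (fmol per mg total protein).
#' @param control_mean Mean concentration of non-dystrophic control tissue.
#' @param lloq Lower limit of quantification (same units).
#' @return Data frame: `conc_input`, `conc` (post-imputation),
#'   `lloq_imputed`, `pct_normal`.
#' @examples
#' lcms_percent_normal(c(100, 4), control_mean = 200, lloq = 10)
#' @export
lcms_percent_normal <- function(conc, control_mean, lloq = 0) {
  if (control_mean <= 0) stop("control_mean must be positive", call. = FALSE)
  if (lloq < 0) stop("lloq must be non-negative", call. = FALSE)
  if (any(conc < 0, na.rm = TRUE))
    stop("negative concentration", call. = FALSE)
  imput <- !is.na(conc) & conc < lloq
  conc2 <- ifelse(imput, 0.5 * lloq, conc)
  data.frame(conc_input = conc, conc = conc2, lloq_imputed = imput,
             pct_normal = 100 * conc2 / control_mean)
}

#' Cohort expression summary per visit
#'
#' Arithmetic mean with a two-sided 95% t-interval over participants for an
#' expression quantity (percent positive fibers, percent of normal, or raw
#' concentration) at each visit. With fewer than two participants the mean
#' is reported without an interval.
#'
#' @param quants Data frame with `id`, `visit` and the value column.
#' @param value Name of the value column (default `"pct_positive_mean"`).
#' @return Data frame: `visit`, `n`, `mean`, `ci_low`, `ci_high`.
#' @export
expression_summary <- function(quants, value = "pct_positive_mean") {
  rows <- lapply(split(quants, quants$visit), function(d) {
    x <- d[[value]]
    x <- x[!is.na(x)]
    n <- length(x)
    m <- if (n) mean(x) else NA_real_
    if (n >= 2L) {
      hw <- qt(0.975, n - 1L) * sd(x) / sqrt(n)
      ci <- m + c(-1, 1) * hw
    } else ci <- c(NA_real_, NA_real_)
    data.frame(visit = d$visit[1], n = n, mean = m,
               ci_low = ci[1], ci_high = ci[2], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  vis <- c("baseline", "month2", "year1")
  out[order(match(out$visit, vis, nomatch = 99L), out$visit), , drop = FALSE]
}
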
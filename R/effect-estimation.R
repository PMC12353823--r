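# Weighted treatment-effect estimation and stratified bootstrap inference.

canonical_endpoints <- c("nsaa_total", "rise_velocity", "run10_velocity",
                         "stair4_velocity", "walk6_distance", "pul", "pfvc")

new_effect_estimate <- function(lsm_t, lsm_e, diff, method,
                                se = NA_real_, ci = c(NA_real_, NA_real_),
                                p = NA_real_, B = NA_integer_,
                                seed = NA_integer_) {
  structure(list(
    ls_mean_treated = lsm_t, ls_mean_external = lsm_e, difference = diff,
    se_boot = se, ci_low = ci[1], ci_high = ci[2], p_one_sided = p,
    B = B, seed = seed, method = method
  ), class = "effect_estimate")
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat(sprintf("<effect_estimate> [%s]\n", x$method))
  cat(sprintf("  LS means: treated %.3f, external %.3f; difference %.3f\n",
              x$ls_mean_treated, x$ls_mean_external, x$difference))
  if (!is.na(x$se_boot))
    cat(sprintf("  bootstrap se %.3f; 95%% BC CI (%.3f, %.3f); one-sided p %.4f (B = %d)\n",
                x$se_boot, x$ci_low, x$ci_high, x$p_one_sided, x$B))
  invisible(x)
}

resolve_weights <- function(outcomes, weights, require_stage = TRUE) {
  if (inherits(weights, "weight_vector")) {
    if (require_stage && !identical(attr(weights, "stage"), "renormalized"))
      stop("weights must be at stage 'renormalized'", call. = FALSE)
    w <- weights$w[match(outcomes$id, weights$id)]
    if (any(is.na(w)))
      stop("weights do not cover all outcome ids", call. = FALSE)
    w
  } else {
    w <- as.numeric(weights)
    if (length(w) != nrow(outcomes))
      stop("weight length does not match outcomes", call. = FALSE)
    w
  }
}

#' IPTW-ATT treatment-effect point estimate
#'
#' Weighted least squares of the 1-year change on a treatment-group factor.
#' With a saturated (two-group) model the least-squares means are exactly
#' the weighted mean change per arm, and the difference (treated minus
#' external) is the IPTW-ATT effect estimate.
#'
#' @param outcomes Data frame with columns `id`, `arm`, `change` for a
#'   single endpoint; changes must be complete.
#' @param weights A renormalized [trim_and_renormalize()] weight vector, or
#'   a bare numeric vector aligned with `outcomes` rows (e.g. unit weights).
#' @return An `effect_estimate` (point part only; see [bootstrap_infer()]
#'   for inference).
#' @examples
#' oc <- data.frame(id = 1:4, arm = rep(c("treated_high", "external"), 2),
#'                  change = c(1, -1, 1, -1))
#' iptw_estimate(oc, rep(1, 4))$difference  # 2
#' @export
iptw_estimate <- function(outcomes, weights) {
  w <- resolve_weights(outcomes, weights)
  treated <- is_treated_arm(outcomes$arm)
  if (!any(treated) || all(treated)) stop("empty arm", call. = FALSE)
  if (any(is.na(outcomes$change))) stop("changes must be complete",
                                        call. = FALSE)
  if (sum(w[treated]) <= 0 || sum(w[!treated]) <= 0)
    stop("weights sum to zero within an arm", call. = FALSE)
  X <- cbind(1, as.numeric(treated))
  fit <- lm.wfit(X, outcomes$change, w)
  lsm_e <- fit$coefficients[1]
  lsm_t <- sum(fit$coefficients)
  new_effect_estimate(unname(lsm_t), unname(lsm_e),
                      unname(fit$coefficients[2]), "iptw")
}

#' Doubly robust (AIPW-style) treatment-effect point estimate
#'
#' Weighted least squares of the change on the treatment indicator plus the
#' propensity-model covariates, using the IPTW-ATT weights. Including the
#' confounders in the weighted outcome regression yields a doubly robust
#' estimate: it is consistent if either the propensity model or the outcome
#' model is correct. Constant covariate columns are dropped (the estimate
#' then reduces to [iptw_estimate()] exactly).
#'
#' @param outcomes Data frame with `id`, `arm`, `change` and the covariate
#'   columns.
#' @param weights As in [iptw_estimate()].
#' @param covariates Covariate column names (default the prespecified four).
#' @return An `effect_estimate` with `method = "aipw"`.
#' @export
aipw_estimate <- function(outcomes, weights,
                          covariates = ps_default_covariates) {
  w <- resolve_weights(outcomes, weights)
  treated <- is_treated_arm(outcomes$arm)
  if (!any(treated) || all(treated)) stop("empty arm", call. = FALSE)
  if (any(!complete.cases(outcomes[c("change", covariates)])))
    stop("changes and covariates must be complete", call. = FALSE)
  Z <- as.matrix(outcomes[covariates])
  keep <- apply(Z, 2L, function(col) var(col) > 0)
  Z <- Z[, keep, drop = FALSE]
  X <- cbind(`(Intercept)` = 1, treat = as.numeric(treated), Z)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[seq(qx$rank + 1L, ncol(X))]]
    stop("collinear covariates in the outcome model: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  fit <- lm.wfit(X, outcomes$change, w)
  cf <- fit$coefficients
  # LS means evaluated at the treated-arm weighted covariate means (the
  # ATT reference population)
  xref <- if (ncol(Z)) colSums(Z[treated, , drop = FALSE] * w[treated]) /
    sum(w[treated]) else numeric(0)
  lsm_t <- cf[1] + cf[2] + sum(cf[-(1:2)] * xref)
  lsm_e <- cf[1] + sum(cf[-(1:2)] * xref)
  new_effect_estimate(unname(lsm_t), unname(lsm_e), unname(cf[2]), "aipw")
}

# ---- fast internal pipeline used by the bootstrap --------------------

# X: covariate matrix (no intercept); returns NA on a degenerate PS fit
pipeline_difference <- function(X, treat, y, trim_quantile, estimator) {
  fit <- logit_fit(cbind(1, X), treat)
  p <- fit$fitted.values
  if (any(p < 1e-10) || any(p > 1 - 1e-10)) return(NA_real_)
  w <- ifelse(treat == 1L, 1, p / (1 - p))
  ext <- treat == 0L
  we <- w[ext]
  cap <- quantile_linear(we, trim_quantile)
  we <- pmin(we, cap)
  w[ext] <- we / sum(we)
  if (estimator == "iptw") {
    sum(y[!ext]) / sum(!ext) - sum(w[ext] * y[ext])
  } else {
    XX <- cbind(1, treat, X)
    lm.wfit(XX, y, w)$coefficients[2]
  }
}

#' Stratified bootstrap inference for the treatment effect
#'
#' Resamples participants with replacement within each arm (arm sizes are
#' design-fixed), re-running the full estimation pipeline -- propensity fit,
#' ATT weights, trimming/renormalization, effect estimate -- in every
#' replicate so that design-stage uncertainty propagates into the interval.
#' Reports the bootstrap standard error, the bias-corrected (BC) percentile
#' 95% interval, and a one-sided empirical p-value computed on the
#' null-centered bootstrap distribution (the proportion of centered
#' replicate differences at or beyond the observed difference in the
#' beneficial direction, floored at `1/(B+1)`).
#'
#' @param data Analysis data frame: `id`, `arm`, the propensity covariates,
#'   and `change` for one endpoint (complete cases).
#' @param B Number of bootstrap replicates (>= 100; default 2000).
#' @param seed Integer seed for the resampling stream.
#' @param estimator `"iptw"` or `"aipw"`.
#' @param trim_quantile Weight-trimming quantile (default 0.95).
#' @param covariates Propensity/outcome covariate columns.
#' @param retry_cap Replicates with a degenerate (separated) propensity fit
#'   are redrawn up to this many times before erroring (default 10).
#' @return A list with `estimate` (an `effect_estimate` carrying se, CI and
#'   p) and `boot` (class `bootstrap_result`: replicate differences, the
#'   bias-correction `z0`, and the percentile levels used).
#' @export
bootstrap_infer <- function(data, B = 2000L, seed,
                            estimator = c("iptw", "aipw"),
                            trim_quantile = 0.95,
                            covariates = ps_default_covariates,
                            retry_cap = 10L) {
  estimator <- match.arg(estimator)
  if (B < 100L) stop("B must be at least 100", call. = FALSE)
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  stopifnot(all(c("id", "arm", "change", covariates) %in% names(data)))
  data <- data[complete.cases(data[c("change", covariates)]), , drop = FALSE]

  treat <- as.integer(is_treated_arm(data$arm))
  X <- as.matrix(data[covariates])
  y <- data$change
  obs_fit <- observed_estimate(data, trim_quantile, estimator, covariates)
  obs <- obs_fit$difference

  it <- which(treat == 1L)
  ie <- which(treat == 0L)
  nt <- length(it)
  ne <- length(ie)
  bs <- with_seed(seed, {
    out <- numeric(B)
    for (b in seq_len(B)) {
      v <- NA_real_
      for (r in seq_len(retry_cap)) {
        idx <- c(it[sample.int(nt, nt, replace = TRUE)],
                 ie[sample.int(ne, ne, replace = TRUE)])
        v <- pipeline_difference(X[idx, , drop = FALSE], treat[idx], y[idx],
                                 trim_quantile, estimator)
        if (!is.na(v)) break
      }
      if (is.na(v))
        stop("degenerate propensity fit in ", retry_cap,
             " consecutive bootstrap redraws", call. = FALSE)
      out[b] <- v
    }
    out
  })

  se <- sd(bs)
  if (se < 1e-12) {
    ci <- c(obs, obs)
    z0 <- 0
    alph <- c(0.025, 0.975)
    p1 <- 1 / (B + 1)
  } else {
    frac_below <- min(max(mean(bs < obs), 1 / (B + 1)), B / (B + 1))
    z0 <- qnorm(frac_below)
    alph <- pnorm(2 * z0 + qnorm(c(0.025, 0.975)))
    ci <- quantile_linear(bs, alph)
    centered <- bs - mean(bs)
    p1 <- max(mean(centered >= obs), 1 / (B + 1))
  }

  est <- new_effect_estimate(obs_fit$ls_mean_treated,
                             obs_fit$ls_mean_external, obs,
                             estimator, se, ci, p1, as.integer(B),
                             as.integer(seed))
  boot <- structure(list(estimates = bs, bias_correction_z0 = z0,
                         percentiles = alph), class = "bootstrap_result")
  list(estimate = est, boot = boot)
}

observed_estimate <- function(data, trim_quantile, estimator, covariates) {
  psfit <- fit_propensity(data, covariates)
  wv <- trim_and_renormalize(att_weights(psfit), trim_quantile)
  if (estimator == "iptw") iptw_estimate(data, wv)
  else aipw_estimate(data, wv, covariates)
}

#' Endpoint battery: effect estimates across the functional endpoints
#'
#' Runs the full weighted analysis for every endpoint present in the
#' outcomes table: unadjusted per-arm summaries (mean, s.d., median of the
#' 1-year change), then the IPTW-ATT (or doubly robust) least-squares
#' means, difference, bootstrap standard error, BC 95% interval and
#' one-sided p. Each endpoint consumes an independent, endpoint-keyed seed
#' stream, so results do not depend on battery order.
#'
#' @param cohort Analysis cohort (treated + selected external) with the
#'   propensity covariate columns.
#' @param outcomes Long outcomes table (`id`, `endpoint`, `baseline`,
#'   `year1`, `change`).
#' @param B,seed,estimator,trim_quantile Passed to [bootstrap_infer()].
#' @return A data frame of class `endpoint_battery`, one row per endpoint,
#'   with an `estimates` attribute holding the full `effect_estimate`
#'   objects.
#' @export
endpoint_battery <- function(cohort, outcomes, B = 2000L, seed,
                             estimator = c("iptw", "aipw"),
                             trim_quantile = 0.95) {
  estimator <- match.arg(estimator)
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  eps <- intersect(canonical_endpoints, unique(outcomes$endpoint))
  if (!length(eps)) stop("no recognised endpoints in outcomes",
                         call. = FALSE)
  ests <- list()
  rows <- lapply(eps, function(ep) {
    oc <- outcomes[outcomes$endpoint == ep, c("id", "change")]
    df <- merge(cohort, oc, by = "id")
    df <- df[complete.cases(df[c("change", ps_default_covariates)]), ]
    treated <- is_treated_arm(df$arm)
    # endpoint-keyed seed: independent of battery order
    ep_seed <- seed + 7919L * match(ep, canonical_endpoints)
    bi <- bootstrap_infer(df, B = B, seed = ep_seed, estimator = estimator,
                          trim_quantile = trim_quantile)
    ests[[ep]] <<- bi$estimate
    e <- bi$estimate
    data.frame(
      endpoint = ep,
      n_treated = sum(treated), n_external = sum(!treated),
      mean_change_treated = mean(df$change[treated]),
      sd_change_treated = sd(df$change[treated]),
      median_change_treated = median(df$change[treated]),
      mean_change_external = mean(df$change[!treated]),
      sd_change_external = sd(df$change[!treated]),
      median_change_external = median(df$change[!treated]),
      ls_mean_treated = e$ls_mean_treated,
      ls_mean_external = e$ls_mean_external,
      difference = e$difference, se_boot = e$se_boot,
      ci_low = e$ci_low, ci_high = e$ci_high,
      p_one_sided = e$p_one_sided,
      stringsAsFactors = FALSE
    )
  })
  structure(do.call(rbind, rows), estimates = ests,
            B = B, seed = seed, method = estimator,
            class = c("endpoint_battery", "data.frame"))
}

#' Age-stratified 1-year changes
#'
#' Splits the treated arm into age strata (default 6-7 and 8-12 years at
#' screening), reporting per-stratum n, mean and s.d. of the change, and
#' the stratum-restricted weighted difference versus the external cohort
#' (external weights renormalized within the stratum).
#'
#' @param cohort Analysis cohort with `age_screening`.
#' @param outcomes Long outcomes table; `endpoint` selects the row set.
#' @param weights Renormalized weight vector for the full cohort.
#' @param strata List of `c(lower, upper)` age bounds (inclusive).
#' @param endpoint Endpoint to stratify (default `"nsaa_total"`).
#' @return Data frame, one row per stratum; empty strata yield `n = 0` rows
#'   with missing statistics.
#' @export
age_stratified_changes <- function(cohort, outcomes, weights,
                                   strata = list(`6-7` = c(6, 7),
                                                 `8-12` = c(8, 12)),
                                   endpoint = "nsaa_total") {
  oc <- outcomes[outcomes$endpoint == endpoint, c("id", "change")]
  df <- merge(cohort, oc, by = "id")
  w <- resolve_weights(df, weights)
  treated <- is_treated_arm(df$arm)
  rows <- lapply(names(strata), function(nm) {
    b <- strata[[nm]]
    # integer-year strata: ages are binned by completed years
    in_str <- floor(df$age_screening) >= b[1] & floor(df$age_screening) <= b[2]
    ti <- treated & in_str & !is.na(df$change)
    ei <- !treated & in_str & !is.na(df$change)
    if (!any(ti)) {
      return(data.frame(stratum = nm, n_treated = 0L,
                        mean_change = NA_real_, sd_change = NA_real_,
                        n_external = sum(ei),
                        weighted_difference = NA_real_,
                        stringsAsFactors = FALSE))
    }
    wd <- if (any(ei))
      mean(df$change[ti]) - weighted_mean(df$change[ei], w[ei])
    else NA_real_
    data.frame(stratum = nm, n_treated = sum(ti),
               mean_change = mean(df$change[ti]),
               sd_change = sd(df$change[ti]),
               n_external = sum(ei),
               weighted_difference = wd,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
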
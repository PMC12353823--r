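# Propensity-score estimation, IPTW-ATT weights, trimming, balance.

ps_default_covariates <- c("age_screening", "nsaa_total_baseline",
                           "rise_velocity", "run10_velocity")

# shared fast logistic fit; family object built once at load time
.binomial_family <- stats::binomial()

logit_fit <- function(X, y, epsilon = 1e-8, maxit = 100L) {
  suppressWarnings(
    glm.fit(X, y, family = .binomial_family,
            control = list(epsilon = epsilon, maxit = maxit))
  )
}

#' Fit the propensity-score model
#'
#' Maximum-likelihood logistic regression of treatment membership on the
#' prespecified baseline covariates (linear terms only): screening age,
#' baseline NSAA total score, rise-from-floor velocity and 10-m run/walk
#' velocity. The fitted probability of treatment per participant feeds
#' [att_weights()].
#'
#' @param cohort Data frame with an `arm` column and the covariate columns.
#' @param covariates Character vector of covariate column names; the default
#'   is the prespecified four. Transformations/interactions are deliberately
#'   not supported here -- construct columns upstream if needed.
#' @return An object of class `ps_fit`: coefficients, per-participant
#'   fitted probabilities `p` (all strictly inside (0, 1)), covariate
#'   names, and a convergence record.
#' @examples
#' study <- generate_study(sim_config(seed = 2, n_treated = 8, n_pool = 40))
#' fit <- fit_propensity(study$participants)
#' range(fit$p)
#' @export
fit_propensity <- function(cohort, covariates = ps_default_covariates) {
  treat <- as.integer(is_treated_arm(cohort$arm))
  if (all(treat == 1L) || all(treat == 0L))
    stop("cohort must contain both treated and external participants",
         call. = FALSE)
  miss <- !complete.cases(cohort[covariates])
  if (any(miss))
    stop("missing covariate values for id(s): ",
         paste(cohort$id[miss], collapse = ", "), call. = FALSE)
  X <- cbind(`(Intercept)` = 1, as.matrix(cohort[covariates]))
  fit <- logit_fit(X, treat)
  p <- fit$fitted.values
  if (any(p < 1e-10) || any(p > 1 - 1e-10)) {
    sep <- separating_covariate(cohort[covariates], treat)
    stop("propensity model did not yield probabilities inside (0, 1); ",
         if (!is.na(sep)) paste0("covariate '", sep,
                                 "' separates the arms perfectly")
         else "the arms are (quasi-)separated", call. = FALSE)
  }
  structure(list(
    coefficients = setNames(fit$coefficients, colnames(X)),
    p = p,
    id = cohort$id,
    treat = treat,
    covariate_names = covariates,
    converged = fit$converged,
    iterations = fit$iter
  ), class = "ps_fit")
}

separating_covariate <- function(covs, treat) {
  for (nm in names(covs)) {
    x <- covs[[nm]]
    if (max(x[treat == 0]) < min(x[treat == 1]) ||
        max(x[treat == 1]) < min(x[treat == 0])) return(nm)
  }
  NA_character_
}

#' @export
print.ps_fit <- function(x, ...) {
  cat("<ps_fit> logistic propensity model\n")
  print(round(x$coefficients, 4))
  cat(sprintf("  fitted p in [%.4f, %.4f]; converged: %s (%d iter)\n",
              min(x$p), max(x$p), x$converged, x$iterations))
  invisible(x)
}

#' IPTW-ATT weights from a propensity fit
#'
#' Treated participants receive weight 1; external-control participants
#' receive the odds of treatment `p / (1 - p)`, standardising the external
#' cohort to the treated covariate distribution (the ATT target).
#'
#' @param psfit A [fit_propensity()] result, or a numeric vector of
#'   treatment probabilities.
#' @param arms Arm labels aligned with the probabilities (taken from the
#'   fit when omitted).
#' @return An object of class `weight_vector`: data frame columns `id`,
#'   `arm`, `p`, `w`, with attributes `stage = "raw"` and `trim_cap = NA`.
#' @examples
#' att_weights(c(0.5, 0.8), arms = c("external", "external"))$w  # 1, 4
#' @export
att_weights <- function(psfit, arms = NULL) {
  if (inherits(psfit, "ps_fit")) {
    p <- psfit$p
    id <- psfit$id
    if (is.null(arms)) arms <- ifelse(psfit$treat == 1L, "treated_high",
                                      "external")
  } else {
    p <- as.numeric(psfit)
    id <- seq_along(p)
    if (is.null(arms)) stop("`arms` required when psfit is a plain vector",
                            call. = FALSE)
  }
  if (any(p <= 0 | p >= 1))
    stop("propensity values must lie strictly inside (0, 1)", call. = FALSE)
  treated <- is_treated_arm(arms)
  w <- ifelse(treated, 1, p / (1 - p))
  structure(
    data.frame(id = id, arm = arms, p = p, w = w, stringsAsFactors = FALSE),
    stage = "raw", trim_cap = NA_real_, class = c("weight_vector",
                                                  "data.frame"))
}

#' Trim extreme external weights and renormalize
#'
#' External-control weights above the 95th percentile of the external
#' weight distribution (linear-interpolation quantile) are set equal to
#' that percentile; each external weight is then divided by the post-trim
#' external total so the external weights sum to 1. Treated weights stay
#' at 1.
#'
#' @param weights A raw-stage [att_weights()] object.
#' @param trim_quantile Trimming quantile (default 0.95).
#' @return The weight vector at stage `"renormalized"`, with the applied
#'   cap stored in the `trim_cap` attribute.
#' @examples
#' wv <- att_weights(c(.5, .5, .5, .5, .99),
#'                   arms = rep("external", 5))
#' attr(trim_and_renormalize(wv), "trim_cap")
#' @export
trim_and_renormalize <- function(weights, trim_quantile = 0.95) {
  if (!identical(attr(weights, "stage"), "raw"))
    stop("weights must be at stage 'raw'", call. = FALSE)
  ext <- !is_treated_arm(weights$arm)
  if (!any(ext)) stop("no external-control weights to trim", call. = FALSE)
  cap <- quantile_linear(weights$w[ext], trim_quantile)
  w <- weights$w
  w[ext] <- pmin(w[ext], cap)
  w[ext] <- w[ext] / sum(w[ext])
  weights$w <- w
  attr(weights, "stage") <- "renormalized"
  attr(weights, "trim_cap") <- cap
  attr(weights, "trim_quantile") <- trim_quantile
  weights
}

#' Covariate balance diagnostics (standardized mean differences)
#'
#' For each covariate the standardized mean difference (SMD) is the treated
#' minus (weighted) external mean divided by the pooled unweighted standard
#' deviation, `sqrt((var_t + var_e) / 2)`; the same denominator is used in
#' the weighted and unweighted columns so the two are comparable.
#'
#' @param cohort Data frame with `arm` and covariate columns.
#' @param weights A renormalized [trim_and_renormalize()] weight vector
#'   aligned with `cohort` by `id`.
#' @param covariates Covariate columns to diagnose.
#' @return An object of class `balance_table`: data frame with columns
#'   `covariate`, `smd_unweighted`, `smd_weighted`, plus a `max_abs` attribute
#'   with the per-column maxima of |SMD|.
#' @examples
#' study <- generate_study(sim_config(seed = 5, n_treated = 8, n_pool = 60))
#' wv <- trim_and_renormalize(att_weights(fit_propensity(study$participants)))
#' balance_table(study$participants, wv)
#' @export
balance_table <- function(cohort, weights,
                          covariates = ps_default_covariates) {
  if (!identical(attr(weights, "stage"), "renormalized"))
    stop("weights must be at stage 'renormalized'", call. = FALSE)
  m <- match(cohort$id, weights$id)
  if (any(is.na(m))) stop("weights do not cover all cohort ids",
                          call. = FALSE)
  w <- weights$w[m]
  treated <- is_treated_arm(cohort$arm)
  rows <- lapply(covariates, function(nm) {
    xt <- cohort[[nm]][treated]
    xe <- cohort[[nm]][!treated]
    wt <- w[treated]
    we <- w[!treated]
    sd_pool <- sqrt((var(xt) + var(xe)) / 2)
    d_un <- mean(xt) - mean(xe)
    d_w <- weighted_mean(xt, wt) - weighted_mean(xe, we)
    if (sd_pool == 0) {
      if (abs(d_un) > 1e-12 || abs(d_w) > 1e-12)
        stop("zero pooled s.d. with unequal means for covariate ", nm,
             call. = FALSE)
      smd_un <- smd_w <- 0
    } else {
      smd_un <- d_un / sd_pool
      smd_w <- d_w / sd_pool
    }
    data.frame(covariate = nm, smd_unweighted = smd_un, smd_weighted = smd_w,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  structure(out,
            max_abs = c(unweighted = max(abs(out$smd_unweighted)),
                        weighted = max(abs(out$smd_weighted))),
            class = c("balance_table", "data.frame"))
}

#' @export
print.balance_table <- function(x, ...) {
  cat("<balance_table> standardized mean differences\n")
  print.data.frame(cbind(x["covariate"],
                         round(x[c("smd_unweighted", "smd_weighted")], 4)),
                   row.names = FALSE)
  m <- attr(x, "max_abs")
  cat(sprintf("  max |SMD|: unweighted %.4f, weighted %.4f\n",
              m[["unweighted"]], m[["weighted"]]))
  invisible(x)
}
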
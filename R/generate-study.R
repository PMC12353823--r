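# Synthetic-data module: participant-level trial + external-pool generator.
#
# Design notes
# - Treated-arm covariates: age ~ U[4,12]; NSAA total, rise velocity and
#   10-m velocity from truncated normals. Pool covariates are exponential
#   tilts of the same distributions (tilted uniform for age; mean-shifted
#   truncated normals with identical truncation bounds), so the true log
#   density ratio is linear and a main-effects logistic PS is exact.
# - 1-year change = control_drift + true_att * treated + beta' (x - mu_t)
#   + Gaussian noise, per endpoint scaled to the endpoint's units.
# - Eligibility: the rise-from-floor rule (<= 7 s) acts as a truncation
#   bound shared by both arms; every other rule fails via independent
#   Bernoulli draws calibrated so that the overall expected pass rate
#   equals eligibility_params$pass_rate.

# canonical endpoint battery with per-endpoint truth (effects/drifts in the
# endpoint's units; anchored to the reference trial's reported battery)
endpoint_truth_defaults <- function(true_att, control_drift, noise_sd) {
  data.frame(
    endpoint = c("nsaa_total", "rise_velocity", "run10_velocity",
                 "stair4_velocity", "walk6_distance", "pul", "pfvc"),
    att   = c(true_att, 0.07, 0.17, 0.02, 17.8, 1.2, 11.0),
    drift = c(control_drift, -0.06, -0.19, -0.01, -10.6, -0.3, -7.8),
    sd_treated  = c(noise_sd[1], 0.08, 0.32, 0.11, 59.9, 2.5, 11.5),
    sd_external = c(noise_sd[2], 0.06, 0.51, 0.12, 58.4, 1.62, 23.1),
    baseline_mean_t = c(25.8, 0.28, 2.29, 0.37, 386.0, 39.4, 95.6),
    baseline_mean_e = c(26.0, 0.22, 1.96, 0.31, 380.0, 37.4, 107.4),
    baseline_sd = c(4, 0.11, 0.55, 0.12, 70, 3, 15),
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic single-arm study with an external control pool
#'
#' Draws a treated cohort and an external pool of placebo participants with
#' confounded baseline covariates, per-visit functional endpoints whose
#' 1-year changes follow a linear outcome model with known true ATT,
#' item-level NSAA vectors whose sums equal the generated totals, and
#' eligibility fields calibrated so a configurable fraction of the pool
#' passes selection. Regenerating with the same [sim_config()] yields an
#' identical study.
#'
#' @param config A [sim_config()] object.
#' @return An object of class `simulated_study`: a list with data frames
#'   `participants`, `visits` (one row per participant x endpoint, columns
#'   baseline/year1/change), `nsaa_items` (wide, one row per participant x
#'   visit), `fibers`, `lcms`, and `truth` (the generating parameters,
#'   including the per-endpoint true effects).
#' @examples
#' study <- generate_study(sim_config(seed = 7, n_treated = 8, n_pool = 40))
#' head(study$participants)
#' @export
generate_study <- function(config) {
  config <- validate_sim_config(config)
  with_seed(config$seed, generate_study_impl(config))
}

generate_study_impl <- function(config) {
  nt <- config$n_treated
  ne <- config$n_pool
  s <- config$confounding_strength
  cm <- config$covariate_model
  sh <- cm$pool_shift

  id <- c(sprintf("T%02d", seq_len(nt)), sprintf("E%03d", seq_len(ne)))
  arm <- rep(c("treated_high", "external"), c(nt, ne))
  treated <- rep(c(1, 0), c(nt, ne))

  # --- baseline covariates ---------------------------------------------
  age <- c(runif(nt, cm$age_range[1], cm$age_range[2]),
           rtilt_unif(ne, cm$age_range[1], cm$age_range[2],
                      sh[["age_tilt"]] * s))
  nsaa0 <- c(rtrunc_norm(nt, cm$nsaa[["mean"]], cm$nsaa[["sd"]],
                         cm$nsaa[["lower"]], cm$nsaa[["upper"]]),
             rtrunc_norm(ne, cm$nsaa[["mean"]] + sh[["nsaa"]] * s,
                         cm$nsaa[["sd"]], cm$nsaa[["lower"]],
                         cm$nsaa[["upper"]]))
  rise <- c(rtrunc_norm(nt, cm$rise[["mean"]], cm$rise[["sd"]],
                        lower = 1 / config$eligibility_params$rise_time_max),
            rtrunc_norm(ne, cm$rise[["mean"]] + sh[["rise"]] * s,
                        cm$rise[["sd"]], lower = 0.02))
  run10 <- c(rtrunc_norm(nt, cm$run10[["mean"]], cm$run10[["sd"]],
                         lower = cm$run10[["lower"]]),
             rtrunc_norm(ne, cm$run10[["mean"]] + sh[["run10"]] * s,
                         cm$run10[["sd"]], lower = cm$run10[["lower"]]))

  # confounder index shared by all endpoints, centred at the treated-arm
  # covariate means (NSAA points)
  beta <- cm$beta
  mu_t <- c(age = mean(cm$age_range),
            nsaa = trunc_norm_mean(cm$nsaa[["mean"]], cm$nsaa[["sd"]],
                                   cm$nsaa[["lower"]], cm$nsaa[["upper"]]),
            rise = trunc_norm_mean(cm$rise[["mean"]], cm$rise[["sd"]],
                                   1 / config$eligibility_params$rise_time_max),
            run10 = trunc_norm_mean(cm$run10[["mean"]], cm$run10[["sd"]],
                                    cm$run10[["lower"]]))
  eta <- beta[["age"]] * (age - mu_t[["age"]]) +
    beta[["nsaa"]] * (nsaa0 - mu_t[["nsaa"]]) +
    beta[["rise"]] * (rise - mu_t[["rise"]]) +
    beta[["run10"]] * (run10 - mu_t[["run10"]])

  # --- eligibility fields ----------------------------------------------
  ep <- config$eligibility_params
  rise_time <- 1 / rise
  # pool pass probability of the rise rule under the generating model
  p_rise <- ptrunc_norm_ge(1 / ep$rise_time_max,
                           cm$rise[["mean"]] + sh[["rise"]] * s,
                           cm$rise[["sd"]], lower = 0.02)
  q_other <- ep$pass_rate / p_rise
  if (q_other > 1)
    stop("eligibility pass_rate unattainable: the rise-from-floor rule ",
         "alone fails more often than 1 - pass_rate", call. = FALSE)
  p_rule <- q_other^(1 / 4)  # lvef, steroid, items, year1-nonmissing

  pool_pass <- function() c(rep(TRUE, nt), runif(ne) < p_rule)
  pass_lvef <- pool_pass()
  pass_ster <- pool_pass()
  pass_items <- pool_pass()
  pass_yr1 <- pool_pass()

  lvef <- ifelse(pass_lvef,
                 rtrunc_norm(nt + ne, 62, 3, lower = 56, upper = 75),
                 rtrunc_norm(nt + ne, 50, 3, lower = 35, upper = 54))
  screening_date <- as.Date("2019-06-15") + floor(runif(nt + ne, 0, 365))
  months_on_steroids <- ifelse(pass_ster, 8 + rexp(nt + ne, 1 / 18), 2)
  steroid_start <- add_months(screening_date, -round(months_on_steroids))

  # optional missingness to exercise the imputation / "data permitting"
  # paths; applied only to otherwise-passing pool members so the expected
  # pass rate is unchanged (imputed steroid dates sit exactly at the
  # 6-month boundary, which is inclusive)
  pool_idx <- which(treated == 0)
  if (ep$missing_steroid_frac > 0) {
    cand <- pool_idx[pass_ster[pool_idx]]
    drop <- cand[runif(length(cand)) < ep$missing_steroid_frac]
    steroid_start[drop] <- NA
  }
  if (ep$missing_lvef_frac > 0) {
    cand <- pool_idx[pass_lvef[pool_idx]]
    drop <- cand[runif(length(cand)) < ep$missing_lvef_frac]
    lvef[drop] <- NA
  }

  # --- outcomes ---------------------------------------------------------
  truth_ep <- endpoint_truth_defaults(config$true_att, config$control_drift,
                                      config$noise_sd)
  visits <- vector("list", nrow(truth_ep))
  nsaa_change <- NULL
  for (k in seq_len(nrow(truth_ep))) {
    tr <- truth_ep[k, ]
    # confounder loading scaled to the endpoint's noise scale (1 for the
    # NSAA change), so confounding persists under a null treatment effect
    lam <- tr$sd_treated / config$noise_sd[1]
    chg <- tr$drift + tr$att * treated + lam * eta +
      rnorm(nt + ne, 0, ifelse(treated == 1, tr$sd_treated, tr$sd_external))
    base <- switch(tr$endpoint,
      nsaa_total = nsaa0,
      rise_velocity = rise,
      run10_velocity = run10,
      rtrunc_norm(nt + ne,
                  ifelse(treated == 1, tr$baseline_mean_t,
                         tr$baseline_mean_e),
                  tr$baseline_sd, lower = 0)
    )
    if (tr$endpoint == "nsaa_total") nsaa_change <- chg
    visits[[k]] <- data.frame(id = id, endpoint = tr$endpoint,
                              baseline = base, year1 = base + chg,
                              change = chg, stringsAsFactors = FALSE)
  }
  visits <- do.call(rbind, visits)

  # --- item-level NSAA --------------------------------------------------
  total0 <- pmin(34L, pmax(0L, as.integer(round(nsaa0))))
  total1 <- pmin(34L, pmax(0L, as.integer(round(nsaa0 + nsaa_change))))
  diff_noise <- config$item_model_params$difficulty_noise_sd
  diff_base <- config$item_model_params$difficulty
  items0 <- matrix(0L, nt + ne, 17)
  items1 <- matrix(0L, nt + ne, 17)
  for (i in seq_len(nt + ne)) {
    d <- diff_base + rnorm(17, 0, diff_noise)
    force_zero <- if (!pass_items[i]) c(2L, 17L) else integer()
    force_min1 <- if (pass_items[i]) 17L else integer()
    b <- alloc_items(total0[i], d, force_zero, force_min1)
    items0[i, ] <- b
    items1[i, ] <- shift_items(b, total1[i], d, force_zero)
  }
  total0 <- as.integer(rowSums(items0))
  total1 <- as.integer(rowSums(items1))
  total1[!pass_yr1] <- NA_integer_

  nsaa_items <- rbind(
    data.frame(id = id, arm = arm, visit = "baseline",
               items_df(items0), stringsAsFactors = FALSE),
    data.frame(id = id, arm = arm, visit = "year1",
               items_df(items1), stringsAsFactors = FALSE)
  )
  nsaa_items[nsaa_items$visit == "year1" &
               nsaa_items$id %in% id[!pass_yr1],
             paste0("item", sprintf("%02d", 1:17))] <- NA_integer_

  participants <- data.frame(
    id = id, arm = arm,
    age_screening = age,
    nsaa_total_baseline = total0,
    rise_velocity = rise, rise_time = rise_time,
    run10_velocity = run10,
    lvef = lvef,
    steroid_start = steroid_start,
    screening_date = screening_date,
    nsaa_total_year1 = total1,
    stringsAsFactors = FALSE
  )

  # --- biopsies (treated arm only) -------------------------------------
  fibers <- do.call(rbind, lapply(c("baseline", "month2", "year1"),
                                  function(v) generate_fibers_impl(config, v)))
  lp <- config$lcms_params
  sdlog <- sqrt(log(1 + lp$conc_cv^2))
  lcms <- do.call(rbind, lapply(names(lp$conc_mean), function(v) {
    mu <- log(lp$conc_mean[[v]]) - sdlog^2 / 2
    data.frame(id = sprintf("T%02d", seq_len(nt)), visit = v,
               conc = exp(rnorm(nt, mu, sdlog)), stringsAsFactors = FALSE)
  }))

  structure(list(
    participants = participants,
    visits = visits,
    nsaa_items = nsaa_items,
    fibers = fibers,
    lcms = lcms,
    truth = list(config = config, endpoint_truth = truth_ep,
                 expected_n_selected = ne * ep$pass_rate,
                 beta = beta, mu_treated = mu_t)
  ), class = "simulated_study")
}

trunc_norm_mean <- function(mean, sd, lower = -Inf, upper = Inf) {
  a <- (lower - mean) / sd
  b <- (upper - mean) / sd
  mean + sd * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
}

items_df <- function(m) {
  colnames(m) <- paste0("item", sprintf("%02d", 1:17))
  as.data.frame(m)
}

# Allocate an integer total in [0, 34] over 17 items scored 0/1/2 by a
# noisy-difficulty greedy fill (easiest items reach 2 first). Constraints:
# items in force_zero stay 0; items in force_min1 are scored >= 1 when the
# total allows it. The returned scores always sum to the allocated total.
alloc_items <- function(total, difficulty, force_zero = integer(),
                        force_min1 = integer()) {
  sc <- integer(17)
  avail <- setdiff(seq_len(17), force_zero)
  total <- min(total, 2L * length(avail))
  force_min1 <- setdiff(intersect(force_min1, avail), force_zero)
  left <- total
  for (j in force_min1) {
    if (left == 0L) break
    sc[j] <- 1L
    left <- left - 1L
  }
  ord <- avail[order(difficulty[avail])]
  for (j in ord) {            # fill easiest first
    if (left == 0L) break
    room <- 2L - sc[j]
    take <- min(room, left)
    sc[j] <- sc[j] + take
    left <- left - take
  }
  sc
}

# Move a baseline item vector towards a new total: upgrades easiest-first
# when the score rises, downgrades hardest-first when it falls, so skills
# persist between visits.
shift_items <- function(base, new_total, difficulty,
                        force_zero = integer()) {
  sc <- base
  avail <- setdiff(seq_len(17), force_zero)
  new_total <- min(new_total, 2L * length(avail))
  delta <- new_total - sum(sc)
  if (delta > 0) {
    ord <- avail[order(difficulty[avail])]
    for (j in rep(ord, 2L)) {
      if (delta == 0L) break
      if (sc[j] < 2L) { sc[j] <- sc[j] + 1L; delta <- delta - 1L }
    }
  } else if (delta < 0) {
    ord <- avail[order(-difficulty[avail])]
    for (j in rep(ord, 2L)) {
      if (delta == 0L) break
      if (sc[j] > 0L) { sc[j] <- sc[j] - 1L; delta <- delta + 1L }
    }
  }
  sc
}

#' Generate a per-fiber stain-density table for one visit
#'
#' Baseline fibers are drawn from the log-normal background distribution
#' only; post-dose fibers come from a two-component mixture in which a
#' configured fraction of fibers expresses mini-dystrophin (a log-normal
#' component shifted well above the background). Two sections are generated
#' per treated participant.
#'
#' @param config A [sim_config()].
#' @param visit One of `"baseline"`, `"month2"`, `"year1"`.
#' @return A `FiberTable`-shaped data frame: `id`, `visit`, `section`
#'   (`"A"`/`"B"`), `fiber`, `msd` (stain density, arbitrary units > 0).
#' @examples
#' fib <- generate_fibers(sim_config(seed = 3, n_treated = 2, n_pool = 4),
#'                        "year1")
#' table(fib$section)
#' @export
generate_fibers <- function(config, visit) {
  config <- validate_sim_config(config)
  visit <- match.arg(visit, c("baseline", "month2", "year1"))
  # visit-specific offset keeps tables reproducible and distinct per visit
  off <- match(visit, c("baseline", "month2", "year1"))
  with_seed(config$seed + 97L * off, generate_fibers_impl(config, visit))
}

generate_fibers_impl <- function(config, visit) {
  fp <- config$fiber_params
  frac <- fp$positive_fraction[[visit]]
  if (is.null(frac) || is.na(frac))
    stop("no positive_fraction configured for visit ", visit, call. = FALSE)
  nt <- config$n_treated
  nf <- fp$n_fibers_section
  n_total <- nt * 2L * nf
  pos <- runif(n_total) < frac
  msd <- ifelse(pos,
                exp(rnorm(n_total, fp$positive_meanlog, fp$positive_sdlog)),
                exp(rnorm(n_total, fp$background_meanlog, fp$background_sdlog)))
  data.frame(
    id = rep(sprintf("T%02d", seq_len(nt)), each = 2L * nf),
    visit = visit,
    section = rep(rep(c("A", "B"), each = nf), nt),
    fiber = rep(seq_len(nf), 2L * nt),
    msd = msd,
    stringsAsFactors = FALSE
  )
}

#' @export
print.simulated_study <- function(x, ...) {
  np <- nrow(x$participants)
  cat("<simulated_study>\n")
  cat(sprintf("  participants: %d (%d treated, %d external pool)\n", np,
              sum(is_treated_arm(x$participants$arm)),
              sum(x$participants$arm == "external")))
  cat(sprintf("  endpoints: %d | fibers: %d rows | lcms: %d rows\n",
              length(unique(x$visits$endpoint)),
              nrow(x$fibers) %||% 0L, nrow(x$lcms) %||% 0L))
  invisible(x)
}
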
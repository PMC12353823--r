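# Weighted estimators and bootstrap inference.

test_that("IPTW estimate equals the difference of weighted means", {
  oc <- data.frame(id = 1:4,
                   arm = rep(c("treated_high", "external"), each = 2),
                   change = c(1, 1, -1, -1))
  e <- iptw_estimate(oc, rep(1, 4))
  expect_equal(e$difference, 2)
  expect_equal(e$ls_mean_treated, 1)
  expect_equal(e$ls_mean_external, -1)

  set.seed(202)
  for (i in 1:25) {
    n <- sample(6:60, 1)
    oc <- data.frame(id = seq_len(n),
                     arm = sample(c("treated_high", "external"), n, TRUE),
                     change = rnorm(n))
    if (length(unique(oc$arm)) < 2) next
    w <- rexp(n) + 0.01
    e <- iptw_estimate(oc, w)
    tr <- oc$arm == "treated_high"
    oracle <- sum(w[tr] * oc$change[tr]) / sum(w[tr]) -
      sum(w[!tr] * oc$change[!tr]) / sum(w[!tr])
    expect_equal(e$difference, oracle, tolerance = 1e-10)
    # scale invariance of per-arm weighted means
    w2 <- ifelse(tr, w, 10 * w)
    expect_equal(iptw_estimate(oc, w2)$difference, oracle,
                 tolerance = 1e-10)
  }
})

test_that("doubly robust estimate reduces to IPTW with constant covariates", {
  set.seed(77)
  n <- 30
  oc <- data.frame(id = 1:n,
                   arm = rep(c("treated_high", "external"), c(10, 20)),
                   change = rnorm(n),
                   age_screening = 8, nsaa_total_baseline = 25,
                   rise_velocity = 0.3, run10_velocity = 2)
  w <- rexp(n) + 0.1
  expect_equal(aipw_estimate(oc, w)$difference,
               iptw_estimate(oc, w)$difference, tolerance = 1e-12)
  # genuine collinearity among non-constant covariates is reported
  oc$age_screening <- rnorm(n)
  oc$nsaa_total_baseline <- 2 * oc$age_screening
  expect_error(aipw_estimate(oc, w), "collinear")
})

test_that("outcome adjustment is doubly robust to a misspecified PS", {
  # weights from a deliberately wrong (constant) PS; the linear outcome
  # model is correct, so the treatment coefficient still recovers the ATT
  ests <- vapply(1:200, function(i) {
    st <- generate_study(sim_config(seed = 9000 + i, n_treated = 30,
                                    n_pool = 60, confounding_strength = 1,
                                    fiber_params =
                                      list(n_fibers_section = 5L)))
    oc <- merge(st$participants,
                st$visits[st$visits$endpoint == "nsaa_total",
                          c("id", "change")], by = "id")
    aipw_estimate(oc, rep(1, nrow(oc)))$difference
  }, numeric(1))
  mc_se <- sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - 3.4), 3 * mc_se)
})

test_that("null generator yields estimates centered at zero", {
  ests <- vapply(1:100, function(i) {
    st <- generate_study(sim_config(seed = 12000 + i, n_treated = 20,
                                    n_pool = 60, true_att = 0,
                                    fiber_params =
                                      list(n_fibers_section = 5L)))
    df <- analysis_frame(st, select = FALSE)
    psf <- fit_propensity(df)
    wv <- trim_and_renormalize(att_weights(psf))
    iptw_estimate(df, wv)$difference
  }, numeric(1))
  expect_lt(abs(mean(ests)), 3 * sd(ests) / sqrt(length(ests)))
})

test_that("constant PS makes the IPTW estimate the unadjusted difference", {
  st <- generate_study(small_config(seed = 61))
  df <- analysis_frame(st, select = FALSE)
  df$age_screening <- 8
  df$nsaa_total_baseline <- 25
  df$rise_velocity <- 0.3
  df$run10_velocity <- 2
  wv <- trim_and_renormalize(att_weights(fit_propensity(df)))
  e <- iptw_estimate(df, wv)
  tr <- df$arm != "external"
  expect_equal(e$difference,
               mean(df$change[tr]) - mean(df$change[!tr]),
               tolerance = 1e-10)
})

test_that("degenerate outcomes give a zero-width bootstrap interval", {
  df <- data.frame(id = 1:20,
                   arm = rep(c("treated_high", "external"), each = 10),
                   age_screening = 8, nsaa_total_baseline = 25,
                   rise_velocity = 0.3, run10_velocity = 2,
                   change = rep(c(2, -1), each = 10))
  bi <- bootstrap_infer(df, B = 100, seed = 1)
  expect_equal(bi$estimate$se_boot, 0)
  expect_equal(bi$estimate$ci_low, 3)
  expect_equal(bi$estimate$ci_high, 3)
  expect_equal(bi$estimate$difference, 3)
})

test_that("bootstrap standard error is Monte-Carlo stable in B", {
  st <- generate_study(small_config(seed = 62, n_treated = 10))
  df <- analysis_frame(st, select = FALSE)
  a <- bootstrap_infer(df, B = 1000, seed = 10)$estimate$se_boot
  b <- bootstrap_infer(df, B = 2000, seed = 11)$estimate$se_boot
  expect_lt(abs(a - b) / b, 0.10)
})

test_that("bias correction reduces to plain percentiles when z0 is zero", {
  st <- generate_study(small_config(seed = 63))
  df <- analysis_frame(st, select = FALSE)
  bi <- bootstrap_infer(df, B = 400, seed = 12)
  bs <- bi$boot$estimates
  z0 <- bi$boot$bias_correction_z0
  # recompute the interval with the fitted z0 forced to zero
  plain <- unname(quantile(bs, c(0.025, 0.975), type = 7))
  shifted <- unname(quantile(bs, pnorm(2 * z0 + qnorm(c(0.025, 0.975))),
                             type = 7))
  expect_equal(c(bi$estimate$ci_low, bi$estimate$ci_high), shifted)
  if (abs(z0) < 1e-12) expect_equal(shifted, plain)
  # p-value bounded below by 1/(B+1) and within [0, 1]
  expect_gte(bi$estimate$p_one_sided, 1 / 401)
  expect_lte(bi$estimate$p_one_sided, 1)
})

test_that("endpoint battery mirrors the study layout", {
  st <- generate_study(small_config(seed = 64))
  sel <- apply_eligibility(impute_steroid_start(st$participants),
                           st$nsaa_items)
  bat <- endpoint_battery(sel$cohort, st$visits, B = 120, seed = 3)
  expect_setequal(bat$endpoint,
                  c("nsaa_total", "rise_velocity", "run10_velocity",
                    "stair4_velocity", "walk6_distance", "pul", "pfvc"))
  tr <- is_treated_arm(sel$cohort$arm)
  oc <- st$visits[st$visits$endpoint == "nsaa_total", ]
  oc <- oc[oc$id %in% sel$cohort$id, ]
  trc <- grepl("^T", oc$id)
  row <- bat[bat$endpoint == "nsaa_total", ]
  expect_equal(row$mean_change_treated, mean(oc$change[trc]))
  expect_equal(row$median_change_external, median(oc$change[!trc]))
  # one-endpoint input gives a one-row battery
  one <- endpoint_battery(sel$cohort,
                          st$visits[st$visits$endpoint == "pfvc", ],
                          B = 120, seed = 3)
  expect_equal(nrow(one), 1L)
  # endpoint-keyed seeding: results identical whatever else is in the table
  expect_equal(one$difference,
               bat$difference[bat$endpoint == "pfvc"])
})

test_that("age strata partition the treated arm", {
  st <- generate_study(small_config(seed = 65, n_treated = 12))
  sel <- apply_eligibility(impute_steroid_start(st$participants),
                           st$nsaa_items)
  wv <- trim_and_renormalize(att_weights(fit_propensity(sel$cohort)))
  strata <- age_stratified_changes(sel$cohort, st$visits, wv,
                                   strata = list(`4-7` = c(4, 7),
                                                 `8-12` = c(8, 12)))
  expect_equal(sum(strata$n_treated), 12L)
  empty <- age_stratified_changes(sel$cohort, st$visits, wv,
                                  strata = list(none = c(40, 50)))
  expect_equal(empty$n_treated, 0L)
  expect_true(is.na(empty$mean_change))
})
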
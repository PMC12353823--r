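# Propensity fitting, ATT weights, trimming, balance diagnostics.

test_that("identical covariates give the marginal treatment probability", {
  cohort <- data.frame(
    id = 1:10, arm = rep(c("treated_high", "external"), c(3, 7)),
    age_screening = 8, nsaa_total_baseline = 25,
    rise_velocity = 0.3, run10_velocity = 2)
  fit <- fit_propensity(cohort)
  expect_equal(fit$p, rep(0.3, 10), tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("propensity coefficients recover a known logistic model", {
  set.seed(101)
  n <- 4000
  X <- cbind(age_screening = runif(n, 4, 12),
             nsaa_total_baseline = rnorm(n, 25, 4),
             rise_velocity = rnorm(n, 0.3, 0.1),
             run10_velocity = rnorm(n, 2, 0.5))
  b <- c(-1.2, 0.15, -0.05, 2.0, 0.4)
  p <- plogis(b[1] + X %*% b[-1])
  cohort <- data.frame(id = 1:n,
                       arm = ifelse(runif(n) < p, "treated_high",
                                    "external"), X)
  fit <- fit_propensity(cohort)
  # independent route: stats::glm supplies the reference fit and its s.e.
  ref <- glm(arm == "treated_high" ~ age_screening + nsaa_total_baseline +
               rise_velocity + run10_velocity, binomial(), data = cohort)
  expect_equal(unname(fit$coefficients), unname(coef(ref)),
               tolerance = 1e-6)
  se <- summary(ref)$coefficients[, "Std. Error"]
  expect_true(all(abs(fit$coefficients - b) < 3 * se))
})

test_that("degenerate propensity inputs error informatively", {
  cohort <- data.frame(id = 1:4, arm = "external",
                       age_screening = 8, nsaa_total_baseline = 25,
                       rise_velocity = 0.3, run10_velocity = 2)
  expect_error(fit_propensity(cohort), "both treated and external")
  sep <- data.frame(id = 1:20,
                    arm = rep(c("treated_high", "external"), each = 10),
                    age_screening = c(rnorm(10, 20), rnorm(10, -20)),
                    nsaa_total_baseline = 25 + rnorm(20),
                    rise_velocity = 0.3, run10_velocity = 2)
  expect_error(fit_propensity(sep), "age_screening")
  na <- sep
  na$arm <- rep(c("treated_high", "external"), 10)
  na$age_screening <- 8
  na$run10_velocity[c(3, 5)] <- NA
  expect_error(fit_propensity(na), "3, 5")
})

test_that("ATT weights are the odds of treatment for externals, 1 for treated", {
  wv <- att_weights(c(0.5, 0.8, 0.9, 0.2),
                    arms = c("external", "external", "treated_high",
                             "external"))
  expect_equal(wv$w, c(1, 4, 1, 0.25))
  expect_identical(attr(wv, "stage"), "raw")
  expect_error(att_weights(c(0, 0.5), arms = rep("external", 2)),
               "strictly inside")
  # permutation equivariance
  p <- c(0.3, 0.6, 0.7, 0.4)
  arms <- c("external", "treated_high", "external", "external")
  perm <- c(3, 1, 4, 2)
  expect_equal(att_weights(p[perm], arms = arms[perm])$w,
               att_weights(p, arms = arms)$w[perm])
})

test_that("trimming caps at the linear-interpolation 95th percentile and renormalizes", {
  # oracle: for (1,1,1,1,100), q95 = 1 + 0.8 * 99 = 80.2
  wv <- att_weights(c(0.5, 0.5, 0.5, 0.5, 100 / 101),
                    arms = rep("external", 5))
  expect_equal(wv$w, c(1, 1, 1, 1, 100))
  out <- trim_and_renormalize(wv)
  expect_equal(attr(out, "trim_cap"), 80.2)
  expect_equal(out$w, c(1, 1, 1, 1, 80.2) / 84.2)
  expect_equal(sum(out$w), 1, tolerance = 1e-12)
  expect_identical(attr(out, "stage"), "renormalized")
  # uniform weights: cap equals the common value, weights 1/n
  u <- att_weights(rep(2 / 3, 4), arms = rep("external", 4))
  expect_equal(trim_and_renormalize(u)$w, rep(0.25, 4))
  expect_error(trim_and_renormalize(out), "stage 'raw'")
})

test_that("trimming never raises a weight and preserves untrimmed ratios", {
  set.seed(55)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    p <- runif(n, 0.05, 0.95)
    arms <- sample(c("treated_high", "external"), n, replace = TRUE,
                   prob = c(0.3, 0.7))
    if (!any(arms == "external")) arms[1] <- "external"
    wv <- att_weights(p, arms = arms)
    out <- trim_and_renormalize(wv)
    ext <- arms == "external"
    scale <- sum(pmin(wv$w[ext], attr(out, "trim_cap")))
    expect_true(all(out$w[ext] <= wv$w[ext] / scale + 1e-12))
    untrimmed <- ext & wv$w <= attr(out, "trim_cap")
    if (sum(untrimmed) >= 2) {
      r_before <- wv$w[untrimmed] / wv$w[untrimmed][1]
      r_after <- out$w[untrimmed] / out$w[untrimmed][1]
      expect_equal(r_after, r_before, tolerance = 1e-10)
    }
    expect_equal(sum(out$w[ext]), 1, tolerance = 1e-12)
    expect_true(all(out$w[!ext] == 1))
  }
})

test_that("SMD definitions behave on constructed groups", {
  cohort <- data.frame(
    id = 1:40, arm = rep(c("treated_high", "external"), each = 20),
    age_screening = rep(8, 40), nsaa_total_baseline = rep(25, 40),
    rise_velocity = rep(0.3, 40), run10_velocity = rep(2, 40))
  unit <- att_weights(rep(0.5, 40), arms = cohort$arm)
  unit <- trim_and_renormalize(unit)
  bt <- balance_table(cohort, unit)
  expect_equal(bt$smd_unweighted, rep(0, 4))
  expect_equal(bt$smd_weighted, rep(0, 4))
  # means 1 vs 0 with both arm s.d.s equal to 1 gives SMD exactly 1
  set.seed(9)
  x <- rnorm(20)
  x <- (x - mean(x)) / sd(x)
  cohort$age_screening <- c(x + 1, x)
  bt2 <- balance_table(cohort, unit)
  expect_equal(bt2$smd_unweighted[1], 1.0, tolerance = 1e-12)
})

test_that("estimated-PS weighting balances confounded covariates", {
  st <- generate_study(sim_config(seed = 77, n_treated = 150, n_pool = 400,
                                  fiber_params =
                                    list(n_fibers_section = 5L)))
  sel <- apply_eligibility(impute_steroid_start(st$participants),
                           st$nsaa_items)
  wv <- trim_and_renormalize(att_weights(fit_propensity(sel$cohort)))
  bt <- balance_table(sel$cohort, wv)
  expect_lt(attr(bt, "max_abs")[["weighted"]],
            attr(bt, "max_abs")[["unweighted"]])
})
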
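# Synthetic-data generator: determinism, ground-truth structure, fixture.

test_that("same configuration reproduces an identical study", {
  a <- generate_study(small_config(seed = 42))
  b <- generate_study(small_config(seed = 42))
  expect_identical(a$participants, b$participants)
  expect_identical(a$visits, b$visits)
  expect_identical(a$nsaa_items, b$nsaa_items)
  expect_identical(a$fibers, b$fibers)
  expect_identical(a$lcms, b$lcms)
  c <- generate_study(small_config(seed = 43))
  expect_false(identical(a$participants, c$participants))
})

test_that("configuration validation rejects degenerate parameters", {
  expect_error(sim_config(seed = 1, n_treated = 1), "n_treated")
  expect_error(sim_config(seed = 1, n_treated = 20, n_pool = 10), "n_pool")
  expect_error(sim_config(seed = 1, noise_sd = 0), "noise_sd")
  expect_error(sim_config(seed = 1,
                          fiber_params = list(positive_fraction =
                                                c(baseline = 1.2))),
               "mixing")
  expect_error(sim_config(seed = 1,
                          fiber_params = list(background_sdlog = -1)),
               "scale")
  expect_error(sim_config(), "seed")
})

test_that("item sums equal the recorded NSAA totals at every visit", {
  st <- generate_study(small_config(seed = 7))
  for (v in c("baseline", "year1")) {
    it <- st$nsaa_items[st$nsaa_items$visit == v, ]
    sums <- rowSums(it[item_cols])
    tot <- st$participants[[paste0("nsaa_total_", v)]][
      match(it$id, st$participants$id)]
    expect_equal(sums[!is.na(tot)], tot[!is.na(tot)],
                 ignore_attr = TRUE)
    expect_true(all(is.na(sums) == is.na(tot)))
    obs <- as.matrix(it[item_cols])
    expect_true(all(obs[!is.na(obs)] %in% 0:2))
    expect_true(all(sums[!is.na(sums)] >= 0 & sums[!is.na(sums)] <= 34))
  }
})

test_that("zero confounding gives exchangeable covariates between arms", {
  st <- generate_study(sim_config(seed = 11, n_treated = 2000,
                                  n_pool = 2000, confounding_strength = 0,
                                  fiber_params =
                                    list(n_fibers_section = 10L)))
  p <- st$participants
  tr <- p$arm != "external"
  for (cv in c("age_screening", "nsaa_total_baseline", "run10_velocity")) {
    d <- mean(p[[cv]][tr]) - mean(p[[cv]][!tr])
    pooled_se <- sqrt(var(p[[cv]][tr]) / sum(tr) +
                        var(p[[cv]][!tr]) / sum(!tr))
    expect_lt(abs(d), 4 * pooled_se)
  }
})

test_that("unadjusted difference recovers the true ATT when confounding is off", {
  # closed-form expectation of the generating model: with no confounding the
  # arms share covariate distributions, so E[diff of mean changes] = ATT
  st <- generate_study(sim_config(seed = 13, n_treated = 3000,
                                  n_pool = 3000, confounding_strength = 0,
                                  fiber_params =
                                    list(n_fibers_section = 10L)))
  ch <- st$visits[st$visits$endpoint == "nsaa_total", ]
  tr <- st$participants$arm[match(ch$id, st$participants$id)] != "external"
  d <- mean(ch$change[tr]) - mean(ch$change[!tr])
  mc_se <- sqrt(var(ch$change[tr]) / sum(tr) +
                  var(ch$change[!tr]) / sum(!tr))
  expect_lt(abs(d - 3.4), 3 * mc_se)
})

test_that("null generator is centered at zero over replicates", {
  diffs <- vapply(1:200, function(i) {
    st <- generate_study(sim_config(seed = 5000 + i, n_treated = 10,
                                    n_pool = 20, true_att = 0,
                                    confounding_strength = 0,
                                    fiber_params =
                                      list(n_fibers_section = 5L)))
    ch <- st$visits[st$visits$endpoint == "nsaa_total", ]
    tr <- grepl("^T", ch$id)
    mean(ch$change[tr]) - mean(ch$change[!tr])
  }, numeric(1))
  expect_lt(abs(mean(diffs)), 3 * sd(diffs) / sqrt(length(diffs)))
})

test_that("fiber tables follow the configured mixture", {
  cfg <- sim_config(seed = 3, n_treated = 5, n_pool = 10,
                    fiber_params = list(n_fibers_section = 1000L,
                                        positive_fraction =
                                          c(baseline = 0, month2 = 0.2,
                                            year1 = 0.35)))
  base <- generate_fibers(cfg, "baseline")
  expect_true(all(base$msd > 0))
  # all baseline fibers from the background component: log-MSD moments
  # match the background parameters within Monte-Carlo error
  n <- nrow(base)
  expect_lt(abs(mean(log(base$msd)) - cfg$fiber_params$background_meanlog),
            3 * cfg$fiber_params$background_sdlog / sqrt(n))
  expect_lt(abs(sd(log(base$msd)) - cfg$fiber_params$background_sdlog), 0.02)
  yr1 <- generate_fibers(cfg, "year1")
  cut <- exp((cfg$fiber_params$background_meanlog +
                cfg$fiber_params$positive_meanlog) / 2)
  frac <- mean(yr1$msd > cut)
  n <- nrow(yr1)
  expect_lt(abs(frac - 0.35), 3 * sqrt(0.35 * 0.65 / n))
  expect_identical(generate_fibers(cfg, "year1"), yr1)
  expect_error(generate_fibers(cfg, "month6"))
})

test_that("worked example reproduces the published skill counts", {
  fx <- worked_example_fixture()
  expect_equal(nrow(fx$participants), 75L)
  expect_equal(sum(fx$participants$arm == "treated_high"), 16L)
  expect_equal(sum(fx$participants$arm == "external"), 59L)
  base <- fx$nsaa_items[fx$nsaa_items$visit == "baseline", ]
  zeros <- rowSums(base[item_cols] == 0) > 0
  expect_equal(sum(zeros & base$arm == "treated_high"), 7L)
  expect_equal(sum(zeros & base$arm == "external"), 17L)
  totals <- rowSums(fx$nsaa_items[item_cols])
  expect_true(all(totals >= 0 & totals <= 34))
})
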
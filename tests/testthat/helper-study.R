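# Shared fixtures: small, fast study configurations.

small_config <- function(seed = 1, n_treated = 8L, n_pool = 40L, ...) {
  sim_config(seed = seed, n_treated = n_treated, n_pool = n_pool,
             fiber_params = list(n_fibers_section = 40L), ...)
}

# analysis data frame (cohort + one endpoint's changes) for estimator tests
analysis_frame <- function(study, endpoint = "nsaa_total",
                           select = TRUE) {
  p <- impute_steroid_start(study$participants)
  cohort <- if (select) apply_eligibility(p, study$nsaa_items)$cohort else p
  oc <- study$visits[study$visits$endpoint == endpoint, c("id", "change")]
  df <- merge(cohort, oc, by = "id")
  df[stats::complete.cases(df[c("change", "age_screening",
                                "nsaa_total_baseline", "rise_velocity",
                                "run10_velocity")]), ]
}

item_cols <- paste0("item", sprintf("%02d", 1:17))

withr_local_tempdir <- function(env = parent.frame()) {
  d <- tempfile("excohort")
  dir.create(d)
  withr::defer(unlink(d, recursive = TRUE), envir = env)
  d
}
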
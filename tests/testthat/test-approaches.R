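zero_spec2 <- function() {
  missingness_spec(dropout = c(0, 0, 0), intermittent = c(0, 0),
                   component_missing = c(0, 0, 0))
}

test_that("all five approaches coincide on complete data", {
  s <- simulate_study(n_trial = 150, n_observational = 200, seed = 71)
  obs <- impose_missingness(s, zero_spec2(), seed = 71)
  cmp <- compare_approaches(obs, options = fast_options(seed = 71))
  for (v in c(6, 12, 24)) {
    est <- cmp$effects$estimate[cmp$effects$visit_month == v]
    expect_lt(max(est) - min(est), 1e-8)
    se <- cmp$effects$se[cmp$effects$visit_month == v]
    expect_lt(max(se) - min(se), 1e-8)
  }
})

test_that("complete-case analysis drops any subject missing at any visit", {
  low <- c(0, 0, 1, 5)      # deep remission
  high <- c(20, 15, 40, 90) # active disease
  profile <- list(low, low, high, high, low, low, high, high, low, high)
  vl <- setNames(lapply(profile, function(p) list(p, p, p)),
                 sprintf("S%02d", 1:10))
  vl$S05 <- list(low, NULL, NULL) # one drop-out after month 6
  panel <- tiny_panel(vl)
  panel$cohort <- rep(rep(c("trial", "observational"), each = 3), 5)
  labels <- classify_missingness(panel)
  baseline <- dplyr::distinct(panel, subject_id, cohort) |>
    dplyr::mutate(x = rep(c(0, 1), 5))
  data <- list(panel = panel, labels = labels, baseline = baseline)
  iptw <- tibble::tibble(subject_id = baseline$subject_id, iptw = 1)
  res <- run_approach("complete_case", data,
                      fast_options(covariates = "x"), iptw = iptw)
  expect_true(all(res$effects$n == 9))
})

test_that("strict censoring with no missingness equals complete case", {
  s <- simulate_study(n_trial = 120, n_observational = 160, seed = 72)
  obs <- impose_missingness(s, zero_spec2(), seed = 72)
  opts <- fast_options(seed = 72)
  iptw <- ecamiss:::compute_iptw(obs, opts)
  cc <- run_approach("complete_case", obs, opts, iptw = iptw)
  sc <- run_approach("strict_censor_ipcw", obs, opts, iptw = iptw)
  expect_equal(sc$effects$estimate, cc$effects$estimate, tolerance = 1e-12)
  expect_equal(sc$effects$se, cc$effects$se, tolerance = 1e-12)
})

test_that("MAR selection pushes the complete-case estimate away from the truth", {
  # drop-out tied to baseline disease activity: completers are selected,
  # the complete-case OR drifts while weighted/imputed approaches track it
  diffs <- replicate(3, NA_real_)
  for (i in 1:3) {
    s <- simulate_study(n_trial = 1500, n_observational = 1500,
                        strategy_log_or = 0.7, seed = 730 + i)
    spec <- missingness_spec(
      dropout = c(0.1, 0.15, 0.2), intermittent = c(0.05, 0.08),
      component_missing = c(0.04, 0.05, 0.08),
      mechanism = "MAR", mar_coefficients = c(das28_0 = -1.2)
    )
    obs <- impose_missingness(s, spec = list(trial = trial_missingness_spec(),
                                             observational = spec),
                              seed = 730 + i)
    opts <- fast_options(seed = 730 + i)
    iptw <- ecamiss:::compute_iptw(obs, opts)
    cc <- run_approach("complete_case", obs, opts, visits = 12, iptw = iptw)
    mi <- run_approach("mi_all", obs, opts, visits = 12, iptw = iptw)
    diffs[i] <- cc$effects$estimate - mi$effects$estimate
  }
  expect_gt(mean(diffs), 0) # CC inflated in the constructed direction
})

test_that("complete-case SEs are no smaller than the advanced approaches on average", {
  ses <- matrix(NA_real_, 3, 2)
  for (i in 1:3) {
    obs <- small_observed(n_trial = 800, n_obs = 1200, seed = 740 + i)
    opts <- fast_options(seed = 740 + i)
    iptw <- ecamiss:::compute_iptw(obs, opts)
    cc <- run_approach("complete_case", obs, opts, visits = 12, iptw = iptw)
    mi <- run_approach("mi_all", obs, opts, visits = 12, iptw = iptw)
    ses[i, ] <- c(cc$effects$se, mi$effects$se)
  }
  expect_gte(mean(ses[, 1]), mean(ses[, 2]))
})

test_that("comparison output has the report shape and internal consistency", {
  obs <- small_observed(seed = 75)
  cmp <- compare_approaches(obs, options = fast_options(seed = 75))
  expect_equal(nrow(cmp$effects), 15)
  expect_setequal(unique(cmp$effects$approach), eca_approaches())
  expect_equal(cmp$effects$or, exp(cmp$effects$estimate))
  expect_true(all(cmp$effects$ci_low <= cmp$effects$or))
  expect_true(all(cmp$effects$or <= cmp$effects$ci_high))
  expect_true(all(cmp$proportions$proportion >= 0 &
                    cmp$proportions$proportion <= 1))
  expect_equal(nrow(cmp$proportions), 30)
  td <- tidy(cmp)
  expect_identical(td, cmp$effects)
})

test_that("stage failures are reported with the approach name", {
  obs <- small_observed(n_trial = 30, n_obs = 40, seed = 76)
  expect_error(
    run_approach("strict_censor_ipcw", obs,
                 fast_options(min_at_risk = 1000, seed = 76)),
    regexp = "strict_censor_ipcw", class = "eca_error_approach"
  )
})
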
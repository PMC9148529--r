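test_that("imputation of complete data returns identical copies", {
  s <- simulate_study(n_trial = 40, n_observational = 60, seed = 51)
  imps <- mice_impute(s$panel, s$baseline, mice_plan(m = 3, seed = 1))
  pans <- imputed_panels(imps)
  expect_length(pans, 3)
  for (pm in pans) expect_identical(pm, s$panel)
})

test_that("the default plan returns ten completed panels", {
  obs <- small_observed(n_trial = 40, n_obs = 60, seed = 52)
  imps <- mice_impute(obs$panel, obs$baseline,
                      mice_plan(m = 10, n_iterations = 2, seed = 2))
  expect_length(imputed_panels(imps), 10)
})

test_that("observed cells are preserved bitwise and no in-scope gaps remain", {
  obs <- small_observed(n_trial = 50, n_obs = 80, seed = 53)
  imps <- mice_impute(obs$panel, obs$baseline,
                      mice_plan(m = 4, n_iterations = 3, seed = 3))
  comp <- c("tjc28", "sjc28", "esr", "pga")
  was_obs <- !is.na(obs$panel[, comp])
  for (pm in imputed_panels(imps)) {
    expect_false(anyNA(pm[, comp]))
    for (j in comp) {
      expect_identical(pm[[j]][was_obs[, j]], obs$panel[[j]][was_obs[, j]])
    }
  }
  # restricted scope reverts out-of-scope cells to missing
  pans_mav <- imputed_panels(imps, "missing_at_visit", obs$labels)
  lab <- obs$labels
  drop_sv <- lab[lab$label == "dropout", c("subject_id", "visit_month")]
  pm <- pans_mav[[1]]
  i <- paste(pm$subject_id, pm$visit_month) %in%
    paste(drop_sv$subject_id, drop_sv$visit_month)
  expect_true(all(is.na(pm$tjc28[i])))
  mav_sv <- lab[lab$label == "missing_at_visit", c("subject_id", "visit_month")]
  j <- paste(pm$subject_id, pm$visit_month) %in%
    paste(mav_sv$subject_id, mav_sv$visit_month)
  expect_false(anyNA(pm[j, comp]))
})

test_that("imputed draws stay in each component's legal range", {
  obs <- small_observed(n_trial = 60, n_obs = 100, seed = 54)
  pans <- imputed_panels(mice_impute(obs$panel, obs$baseline,
                                     mice_plan(m = 2, n_iterations = 3, seed = 4)))
  for (pm in pans) {
    expect_true(all(pm$tjc28 >= 0 & pm$tjc28 <= 28 & pm$tjc28 == round(pm$tjc28)))
    expect_true(all(pm$esr > 0))
    expect_true(all(pm$pga >= 0 & pm$pga <= 100))
  }
})

test_that("MCAR imputation recovers the pre-deletion mean with B > 0", {
  s <- simulate_study(n_trial = 100, n_observational = 4000, seed = 55)
  spec <- missingness_spec(dropout = c(0, 0, 0), intermittent = c(0, 0),
                           component_missing = c(0.3, 0, 0))
  zero <- missingness_spec(dropout = c(0, 0, 0), intermittent = c(0, 0),
                           component_missing = c(0, 0, 0))
  obs <- impose_missingness(s, spec = list(trial = zero, observational = spec),
                            seed = 55)
  imps <- mice_impute(obs$panel, obs$baseline,
                      mice_plan(m = 5, n_iterations = 5, seed = 5))
  pans <- imputed_panels(imps)
  v6 <- s$panel$visit_month == 6 & s$panel$cohort == "observational"
  truth_mean <- mean(s$panel$esr[v6])
  per_m <- vapply(pans, function(pm) {
    mean(pm$esr[pm$visit_month == 6 & pm$cohort == "observational"])
  }, numeric(1))
  expect_lt(abs(mean(per_m) - truth_mean), 1.0)
  expect_gt(sd(per_m), 0)
})

test_that("increasing delta monotonically lowers the imputed remission rate", {
  obs <- small_observed(n_trial = 60, n_obs = 400, seed = 56)
  rates <- vapply(c(0, 0.4, 0.8), function(d) {
    imps <- mice_impute(obs$panel, obs$baseline,
                        mice_plan(m = 3, n_iterations = 3, delta = d, seed = 6))
    mean(vapply(imputed_panels(imps), function(pm) {
      sc <- add_das28(pm)
      mean(sc$remission[sc$cohort == "observational"])
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(rates) < 0))
})

test_that("a variable with no observed values is rejected", {
  obs <- small_observed(n_trial = 30, n_obs = 40, seed = 57)
  p <- obs$panel
  p$pga[p$visit_month == 24] <- NA
  expect_error(mice_impute(p, obs$baseline, mice_plan(m = 2, seed = 7)),
               class = "eca_error_impute")
})

test_that("Rubin pooling matches the hand-computed example", {
  rp <- rubins_pool(c(0.5, 0.7), c(0.04, 0.04))
  expect_equal(rp$qbar, 0.6, tolerance = 1e-12)
  expect_equal(rp$b, 0.02, tolerance = 1e-12)
  expect_equal(rp$t, 0.07, tolerance = 1e-12)
  expect_equal(rp$se, sqrt(0.07), tolerance = 1e-12)
  expect_equal(round(rp$se, 5), 0.26458)
})

test_that("degenerate pooling cases behave as stated", {
  rp <- rubins_pool(c(0.4, 0.4, 0.4), c(0.09, 0.09, 0.09))
  expect_equal(rp$qbar, 0.4)
  expect_equal(rp$b, 0)
  expect_equal(rp$t, 0.09)
  expect_equal(rp$df, Inf)
  rp2 <- rubins_pool(c(0, 0), c(1, 1))
  expect_equal(rp2$qbar, 0)
  expect_equal(rp2$t, 1)
  expect_error(rubins_pool(0.5, 0.04), class = "eca_error_pool")
  expect_error(rubins_pool(c(0.5, NA), c(0.1, 0.1)), class = "eca_error_pool")
})

test_that("Barnard-Rubin df shrinks with finite complete-data df", {
  rp_inf <- rubins_pool(c(0.5, 0.7, 0.6), c(0.04, 0.04, 0.04))
  rp_fin <- rubins_pool(c(0.5, 0.7, 0.6), c(0.04, 0.04, 0.04), dfcom = 50)
  expect_lt(rp_fin$df, rp_inf$df)
  expect_lt(rp_fin$df, 50)
})

test_that("pooled MI interval covers the true log OR across replicates", {
  hits <- 0L
  n_rep <- 200
  for (i in seq_len(n_rep)) {
    s <- simulate_study(n_trial = 500, n_observational = 500,
                        strategy_log_or = 0.7, seed = 7000 + i)
    spec <- missingness_spec(
      dropout = c(0.03, 0.05, 0.1), intermittent = c(0.07, 0.1),
      component_missing = c(0.04, 0.05, 0.08),
      mechanism = "MAR", mar_coefficients = c(das28_0 = 0.5)
    )
    obs <- impose_missingness(s, spec, seed = 7000 + i)
    res <- run_approach("mi_all", obs, fast_options(m = 5, seed = 7000 + i),
                        visits = 12)
    eff <- res$effects
    hits <- hits + as.integer(abs(eff$estimate - 0.7) <= 2 * eff$se)
  }
  expect_gte(hits / n_rep, 0.9)
})
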
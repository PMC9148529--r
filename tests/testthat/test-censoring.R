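# Build a one-cohort monotone censoring problem with known hazards:
# n subjects, censor exactly k6 at visit 6 and k12 (of the remaining) at 12.
counted_censoring <- function(n, k6, k12) {
  vl <- lapply(seq_len(n), function(i) {
    if (i <= k6) list(NULL, NULL, NULL)
    else if (i <= k6 + k12) list(obs_visit(), NULL, NULL)
    else list(obs_visit(), obs_visit(), obs_visit())
  })
  names(vl) <- sprintf("S%04d", seq_len(n))
  panel <- tiny_panel(vl)
  labels <- classify_missingness(panel)
  baseline <- tibble::tibble(
    subject_id = sprintf("S%04d", seq_len(n)), cohort = "observational",
    das28_0 = 5, age = 55
  )
  list(panel = panel, labels = labels, baseline = baseline)
}

test_that("strict censoring fires at the first non-monotone event", {
  p <- tiny_panel(list(A = list(obs_visit(), partial_visit(), obs_visit())))
  cens <- artificial_censor(p, classify_missingness(p), "strict")
  expect_equal(cens$censor_table$censor_visit, 12)
  expect_true(all(is.na(cens$panel$tjc28[cens$panel$visit_month >= 12])))

  p2 <- tiny_panel(list(A = list(NULL, obs_visit(), obs_visit())))
  cens2 <- artificial_censor(p2, classify_missingness(p2), "strict")
  expect_equal(cens2$censor_table$censor_visit, 6)
})

test_that("fully observed subjects are never censored and the panel is unchanged", {
  p <- tiny_panel(list(A = list(obs_visit(), obs_visit(), obs_visit())))
  cens <- artificial_censor(p, classify_missingness(p), "strict")
  expect_true(is.na(cens$censor_table$censor_visit))
  expect_equal(cens$panel, p)
})

test_that("censored output always has a monotone pattern", {
  obs <- small_observed(seed = 41)
  # rules that convert every non-monotone gap to drop-out
  for (rule in c("strict", "intermittent_only")) {
    lab <- classify_missingness(artificial_censor(obs$panel, obs$labels, rule)$panel)
    expect_false(any(lab$label == "intermittent"), info = rule)
  }
  # strict censoring also removes partially missing visits
  lab <- classify_missingness(artificial_censor(obs$panel, obs$labels, "strict")$panel)
  expect_false(any(lab$label == "missing_at_visit"))
  expect_error(artificial_censor(obs$panel, obs$labels, "bogus"))
})

test_that("an intercept-only hazard is the censored proportion and weights conserve n", {
  cc <- counted_censoring(1000, k6 = 200, k12 = 0)
  cens <- artificial_censor(cc$panel, cc$labels, "strict")
  models <- fit_censoring_models(cens, cc$baseline, predictors = character(0))
  h6 <- models$hazards$hazard[models$hazards$visit_month == 6]
  expect_equal(unique(round(h6, 10)), 0.20)
  w <- ipcw_weights(models, stabilized = FALSE)
  w24 <- w$ipcw[w$visit_month == 24]
  expect_equal(unique(round(w24, 10)), 1.25)
  expect_equal(sum(w$ipcw[w$visit_month == 6]), 1000) # 800 x 1.25
  # stabilized weights are exactly 1 under an intercept-only model
  ws <- ipcw_weights(models, stabilized = TRUE)
  expect_true(all(abs(ws$ipcw - 1) < 1e-12))
})

test_that("sequential hazards multiply into the cumulative weight", {
  cc <- counted_censoring(1000, k6 = 100, k12 = 90) # 0.1 then 0.1
  cens <- artificial_censor(cc$panel, cc$labels, "strict")
  models <- fit_censoring_models(cens, cc$baseline, predictors = character(0))
  w <- ipcw_weights(models, stabilized = FALSE)
  expect_equal(unique(round(w$ipcw[w$visit_month == 24], 7)),
               round(1 / (0.9 * 0.9), 7))
})

test_that("no censoring events yield unit weights", {
  cc <- counted_censoring(50, 0, 0)
  cens <- artificial_censor(cc$panel, cc$labels, "strict")
  models <- fit_censoring_models(cens, cc$baseline,
                                 predictors = character(0), min_at_risk = 5)
  w <- ipcw_weights(models)
  expect_true(all(w$ipcw == 1))
})

test_that("too-small risk sets raise an informative error", {
  cc <- counted_censoring(10, 2, 0)
  cens <- artificial_censor(cc$panel, cc$labels, "strict")
  expect_error(fit_censoring_models(cens, cc$baseline, min_at_risk = 50),
               class = "eca_error_risk_set")
})

test_that("MAR drop-out coefficients are recovered by the censoring model", {
  s <- simulate_study(n_trial = 100, n_observational = 50000, seed = 42)
  spec <- missingness_spec(
    dropout = c(0.15, 0.1, 0), intermittent = c(0, 0),
    component_missing = c(0, 0, 0),
    mechanism = "MAR", mar_coefficients = c(das28_0 = 0.8)
  )
  zero <- missingness_spec(dropout = c(0, 0, 0), intermittent = c(0, 0),
                           component_missing = c(0, 0, 0))
  obs <- impose_missingness(s, spec = list(trial = zero, observational = spec),
                            seed = 42)
  cens <- artificial_censor(obs$panel, obs$labels, "strict")
  models <- fit_censoring_models(cens, obs$baseline,
                                 predictors = "das28_0")
  cf <- models$models[["observational 6"]]
  expect_lt(abs(cf[["das28_0"]] - 0.8), 0.1)
})

test_that("monotone precondition is enforced on tampered panels", {
  obs <- small_observed(seed = 43)
  cens <- artificial_censor(obs$panel, obs$labels, "strict")
  cid <- cens$censor_table$subject_id[!is.na(cens$censor_table$censor_visit)][1]
  cv <- cens$censor_table$censor_visit[cens$censor_table$subject_id == cid]
  bad <- cens
  i <- which(bad$panel$subject_id == cid & bad$panel$visit_month >= cv)[1]
  bad$panel$tjc28[i] <- 3
  expect_error(fit_censoring_models(bad, obs$baseline, min_at_risk = 5),
               class = "eca_error_monotone")
})
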
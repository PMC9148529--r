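zero_spec <- function() {
  missingness_spec(dropout = c(0, 0, 0), intermittent = c(0, 0),
                   component_missing = c(0, 0, 0))
}

test_that("zero probabilities leave the panel untouched and all labels observed", {
  s <- simulate_study(n_trial = 50, n_observational = 70, seed = 21)
  obs <- impose_missingness(s, zero_spec(), seed = 1)
  expect_identical(obs$panel, s$panel)
  expect_true(all(obs$labels$label == "observed"))
})

test_that("imposition is reproducible and seed-sensitive", {
  s <- simulate_study(n_trial = 80, n_observational = 80, seed = 22)
  o1 <- impose_missingness(s, observational_missingness_spec(), seed = 9)
  o2 <- impose_missingness(s, observational_missingness_spec(), seed = 9)
  o3 <- impose_missingness(s, observational_missingness_spec(), seed = 10)
  expect_identical(o1$panel, o2$panel)
  expect_identical(o1$labels, o2$labels)
  expect_false(identical(o1$panel, o3$panel))
})

test_that("trial-preset hazards give the target cumulative drop-out rates", {
  s <- simulate_study(n_trial = 100000, n_observational = 100, seed = 23)
  obs <- impose_missingness(
    s, spec = list(trial = trial_missingness_spec(),
                   observational = zero_spec()),
    seed = 23
  )
  lab <- obs$labels[obs$labels$cohort == "trial", ]
  cum <- vapply(c(6, 12, 24), function(v) {
    mean(lab$label[lab$visit_month == v] == "dropout")
  }, numeric(1))
  # closed form 1 - prod(1 - hazard): 0.016, 0.064, 0.101
  expect_lt(max(abs(cum - c(0.016, 0.0642, 0.1016))), 0.005)
})

test_that("MCAR component-missing hits its nominal per-visit rate", {
  s <- simulate_study(n_trial = 100, n_observational = 100000, seed = 24)
  spec <- missingness_spec(dropout = c(0, 0, 0), intermittent = c(0, 0),
                           component_missing = c(0.04, 0, 0))
  obs <- impose_missingness(s, spec = list(trial = zero_spec(),
                                           observational = spec), seed = 24)
  lab <- obs$labels[obs$labels$cohort == "observational", ]
  frac <- mean(lab$label[lab$visit_month == 6] == "missing_at_visit")
  expect_lt(abs(frac - 0.04), 0.003)
  # 1-3 components missing at such visits, never all four
  mav <- lab$subject_id[lab$visit_month == 6 & lab$label == "missing_at_visit"]
  rows <- obs$panel[obs$panel$subject_id %in% mav & obs$panel$visit_month == 6, ]
  nmiss <- rowSums(is.na(rows[, c("tjc28", "sjc28", "esr", "pga")]))
  expect_true(all(nmiss >= 1 & nmiss <= 3))
})

test_that("intermittent probability at the final visit is rejected", {
  expect_error(
    missingness_spec(intermittent = c(`6` = 0.1, `12` = 0.1, `24` = 0.1)),
    class = "eca_error_spec"
  )
  expect_error(missingness_spec(dropout = c(-0.1, 0, 0)),
               class = "eca_error_spec")
})

test_that("classifier reproduces ground-truth labels on random draws", {
  for (i in 1:20) {
    s <- simulate_study(n_trial = 60, n_observational = 90, seed = 300 + i)
    spec <- missingness_spec(
      dropout = runif(3, 0, 0.3), intermittent = runif(2, 0, 0.25),
      component_missing = runif(3, 0, 0.2)
    )
    obs <- impose_missingness(s, spec, seed = 400 + i)
    cl <- classify_missingness(obs$panel)
    truth <- dplyr::arrange(obs$labels, subject_id, visit_month)
    expect_identical(as.character(cl$label), as.character(truth$label))
  }
})

test_that("MAR drop-out coefficients are recovered by logistic regression", {
  s <- simulate_study(n_trial = 100, n_observational = 50000, seed = 26)
  spec <- missingness_spec(
    dropout = c(0.15, 0, 0), intermittent = c(0, 0),
    component_missing = c(0, 0, 0),
    mechanism = "MAR", mar_coefficients = c(das28_0 = 0.8)
  )
  obs <- impose_missingness(s, spec = list(trial = zero_spec(),
                                           observational = spec), seed = 26)
  lab <- obs$labels[obs$labels$cohort == "observational" &
                      obs$labels$visit_month == 6, ]
  bl <- obs$baseline[match(lab$subject_id, obs$baseline$subject_id), ]
  fit <- glm(I(lab$label == "dropout") ~ bl$das28_0, family = binomial())
  expect_lt(abs(coef(fit)[2] - 0.8), 0.1)
})

test_that("under MCAR the drop-out indicator is independent of baseline DAS28", {
  s <- simulate_study(n_trial = 100, n_observational = 50000, seed = 27)
  spec <- missingness_spec(dropout = c(0.15, 0, 0), intermittent = c(0, 0),
                           component_missing = c(0, 0, 0))
  obs <- impose_missingness(s, spec = list(trial = zero_spec(),
                                           observational = spec), seed = 27)
  lab <- obs$labels[obs$labels$cohort == "observational" &
                      obs$labels$visit_month == 6, ]
  bl <- obs$baseline[match(lab$subject_id, obs$baseline$subject_id), ]
  fit <- glm(I(lab$label == "dropout") ~ bl$das28_0, family = binomial())
  expect_lt(abs(coef(fit)[2]), 0.1)
})

test_that("MNAR delta tilts drop-out towards high current disease activity", {
  s <- simulate_study(n_trial = 100, n_observational = 20000, seed = 28)
  spec <- missingness_spec(dropout = c(0.2, 0, 0), intermittent = c(0, 0),
                           component_missing = c(0, 0, 0),
                           mechanism = "MNAR", mnar_delta = 0.8)
  obs <- impose_missingness(s, spec = list(trial = zero_spec(),
                                           observational = spec), seed = 28)
  lab <- obs$labels[obs$labels$cohort == "observational" &
                      obs$labels$visit_month == 6, ]
  latent <- add_das28(obs$latent)
  d6 <- latent$das28[latent$visit_month == 6][
    match(lab$subject_id, latent$subject_id[latent$visit_month == 6])]
  drop6 <- lab$label == "dropout"
  expect_gt(mean(d6[drop6]), mean(d6[!drop6]) + 0.3)
})
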
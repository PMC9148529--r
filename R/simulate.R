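# Synthetic two-cohort generator with known ground truth.
#
# Baseline covariates come from simple parametric families (normal,
# lognormal, Bernoulli) with means in the ranges typical of early-RA
# inception cohorts; per-cohort location shifts induce confounding. Latent
# remission at each visit follows a logistic model in the strategy
# indicator, standardised baseline covariates and a subject-level random
# intercept. Because the marginal odds ratio is non-collapsible, the visit
# intercepts and the strategy coefficient are calibrated numerically so that
# the *marginal* (population-averaged) log OR over the pooled sample equals
# the requested value exactly; that marginal log OR is the estimand the
# IPTW-weighted analyses target, and the generator records it as the truth.

# Reference distributions; `kind` controls how a covariate_shift entry is
# applied: additive for normal, additive on the log scale for lognormal,
# additive on the probability for binary.
eca_reference_covariates <- function() {
  tibble::tribble(
    ~name,         ~kind,       ~p1,      ~p2,   ~lo,  ~hi, ~digits,
    "age",         "normal",    55,       13,    18,   90,  0,
    "female",      "binary",    0.66,     NA,    NA,   NA,  NA,
    "symptom_dur", "lognormal", log(6),   0.8,   0.5,  120, 1,
    "higher_edu",  "binary",    0.40,     NA,    NA,   NA,  NA,
    "rf_pos",      "binary",    0.65,     NA,    NA,   NA,  NA,
    "acpa_pos",    "binary",    0.70,     NA,    NA,   NA,  NA,
    "esr_0",       "lognormal", log(18),  0.6,   1,    120, 1,
    "crp_0",       "lognormal", log(8),   0.9,   0.1,  200, 1,
    "sjc28_0",     "normal",    8,        4,     0,    28,  0,
    "tjc28_0",     "normal",    8,        5,     0,    28,  0,
    "pga_0",       "normal",    48,       20,    0,    100, 0,
    "phga_0",      "normal",    40,       18,    0,    100, 0,
    "comorbid",    "binary",    0.35,     NA,    NA,   NA,  NA,
    "smoker",      "binary",    0.20,     NA,    NA,   NA,  NA,
    "fatigue_0",   "normal",    45,       22,    0,    100, 0,
    "eq5d_0",      "normal",    0.65,     0.20, -0.5,  1,   3
  )
}

# Fixed standardisation constants so both cohorts share one covariate scale.
eca_covariate_scale <- function() {
  tibble::tribble(
    ~name,        ~center, ~scale,
    "age",         55,      13,
    "das28_0",     5.0,     1.1,
    "eq5d_0",      0.65,    0.20,
    "fatigue_0",   45,      22,
    "crp_0",       8,       10,
    "acpa_pos",    0.70,    1,
    "smoker",      0.20,    1
  )
}

#' Default conditional effects of baseline covariates on remission
#'
#' Log-odds coefficients per standardised unit, applied identically in both
#' cohorts; baseline DAS28 is the dominant prognostic factor.
#' @return Named numeric vector.
#' @export
eca_default_outcome_coefs <- function() {
  c(das28_0 = -0.60, age = -0.15, acpa_pos = -0.15, smoker = -0.15,
    eq5d_0 = 0.15, fatigue_0 = -0.10)
}

#' Default observational-cohort covariate shift
#'
#' Location offsets (probability offsets for binary covariates) applied to
#' the observational cohort relative to the shared reference distribution,
#' producing moderate baseline imbalance for IPTW to remove.
#' @return Named numeric vector.
#' @export
eca_default_shift <- function() {
  c(age = -2, higher_edu = -0.05, pga_0 = 5, fatigue_0 = 5, smoker = 0.05)
}

#' Cohort generator configuration
#'
#' @param cohort_id `"trial"` or `"observational"`.
#' @param n_subjects Number of subjects (>= 2).
#' @param covariate_shift Named numeric vector of location offsets relative
#'   to the reference distributions (probability offsets for binary
#'   covariates, log-scale offsets for lognormal ones); `NULL` for none.
#' @param strategy_log_or True marginal log odds ratio of remission (trial
#'   vs observational) per visit; length 3 or scalar.
#' @param p_remission Target marginal remission probability in the
#'   observational strategy per visit.
#' @param outcome_coefs Named log-odds coefficients of standardised baseline
#'   covariates on remission.
#' @param random_intercept_sd SD of the subject-level random intercept.
#' @param seed Integer seed; the same config always yields identical tables.
#' @return An `eca_cohort_config` list.
#' @export
cohort_config <- function(cohort_id = c("observational", "trial"),
                          n_subjects = 328,
                          covariate_shift = NULL,
                          strategy_log_or = c(`6` = 0.4, `12` = 0.7, `24` = 0.4),
                          p_remission = c(`6` = 0.35, `12` = 0.45, `24` = 0.55),
                          outcome_coefs = eca_default_outcome_coefs(),
                          random_intercept_sd = 0.8,
                          seed = 1L) {
  cohort_id <- arg_match(cohort_id)
  if (!is.numeric(n_subjects) || n_subjects < 2) {
    abort("n_subjects must be >= 2", class = "eca_error_config")
  }
  strategy_log_or <- rep_len(strategy_log_or, 3)
  p_remission <- rep_len(p_remission, 3)
  if (!all(is.finite(strategy_log_or)) || !all(is.finite(p_remission)) ||
      (!is.null(covariate_shift) && !all(is.finite(covariate_shift)))) {
    abort("non-finite generator parameters", class = "eca_error_config")
  }
  if (!is.null(covariate_shift)) {
    unknown <- setdiff(names(covariate_shift), eca_reference_covariates()$name)
    if (length(unknown)) {
      abort(sprintf("unknown covariate in shift: %s", paste(unknown, collapse = ", ")),
            class = "eca_error_config")
    }
  }
  structure(
    list(
      cohort_id = cohort_id, n_subjects = as.integer(n_subjects),
      covariate_shift = covariate_shift,
      strategy_log_or = setNames(strategy_log_or, eca_visits()),
      p_remission = setNames(p_remission, eca_visits()),
      outcome_coefs = outcome_coefs,
      random_intercept_sd = random_intercept_sd,
      seed = as.integer(seed)
    ),
    class = "eca_cohort_config"
  )
}

draw_baseline <- function(n, cohort_id, shift = NULL, id_prefix = NULL) {
  ref <- eca_reference_covariates()
  out <- vector("list", nrow(ref))
  names(out) <- ref$name
  for (i in seq_len(nrow(ref))) {
    r <- ref[i, ]
    off <- if (!is.null(shift) && r$name %in% names(shift)) shift[[r$name]] else 0
    x <- switch(r$kind,
      normal = rnorm(n, r$p1 + off, r$p2),
      lognormal = exp(rnorm(n, r$p1 + off, r$p2)),
      binary = as.numeric(runif(n) < clamp(r$p1 + off, 0.01, 0.99))
    )
    if (r$kind != "binary") {
      x <- clamp(x, r$lo, r$hi)
      x <- round(x, r$digits)
      if (r$name %in% c("esr_0", "crp_0")) x <- pmax(x, r$lo)
    }
    out[[r$name]] <- x
  }
  pre <- id_prefix %||% toupper(substr(cohort_id, 1, 1))
  baseline <- tibble(
    subject_id = sprintf("%s%05d", pre, seq_len(n)),
    cohort = cohort_id
  )
  baseline <- dplyr::bind_cols(baseline, as_tibble(out))
  mutate(baseline,
         das28_0 = das28(.data$tjc28_0, .data$sjc28_0, .data$esr_0, .data$pga_0))
}

# Linear predictor offset: standardised covariate effects + random intercept.
baseline_offset <- function(baseline, coefs, u) {
  sc <- eca_covariate_scale()
  off <- u
  for (nm in names(coefs)) {
    row <- sc[sc$name == nm, ]
    if (nrow(row) == 0) row <- tibble(center = mean(baseline[[nm]]), scale = sd(baseline[[nm]]))
    off <- off + coefs[[nm]] * (baseline[[nm]] - row$center) / row$scale
  }
  off
}

# Calibrate the visit intercept and strategy coefficient against the sample
# of offsets so the marginal probabilities and marginal log OR are exact.
calibrate_visit <- function(offsets, p0, log_or) {
  a <- uniroot(function(a) mean(plogis(a + offsets)) - p0,
               lower = -20, upper = 20, tol = 1e-10)$root
  b <- uniroot(function(b) {
    qlogis(mean(plogis(a + b + offsets))) - qlogis(p0) - log_or
  }, lower = -20, upper = 20, tol = 1e-10)$root
  c(alpha = a, beta = b)
}

# Decompose a target DAS28 score into components whose recomputed score
# stays on the same side of the remission cutoff. Joint counts and PGA are
# integers; ESR (1 decimal, >= 1) absorbs the residual exactly, with
# overflow above ESR ~ 140 pushed back into the bounded components.
score_to_components <- function(s) {
  n <- length(s)
  g <- matrix(stats::rgamma(4L * n, shape = rep(c(2.2, 1.8, 2.6, 1.6), each = n)),
              n, 4)
  pr <- g / rowSums(g)
  tj <- clamp(round((s * pr[, 1] / 0.56)^2), 0, 28)
  sj <- clamp(round((s * pr[, 2] / 0.28)^2), 0, 28)
  pg <- clamp(round(s * pr[, 4] / 0.014), 0, 100)
  # ordered repair so the ESR term is non-negative
  tj <- pmin(tj, floor((s / 0.56)^2))
  rem <- s - 0.56 * sqrt(tj)
  sj <- pmin(sj, floor((rem / 0.28)^2))
  rem <- rem - 0.28 * sqrt(sj)
  pg <- pmin(pg, floor(rem / 0.014))
  t3 <- rem - 0.014 * pg
  t3max <- 0.70 * log(140)
  over <- t3 > t3max
  if (any(over)) {
    pg[over] <- pmin(100, pg[over] + ceiling((t3[over] - t3max) / 0.014))
    t3[over] <- rem[over] - 0.014 * pg[over]
    still <- t3 > t3max + 1e-12
    if (any(still)) { # rare very-high scores: widen the swollen joint count
      need <- (t3[still] - t3max) / 0.28 + sqrt(sj[still])
      sj[still] <- pmin(28, ceiling(need^2))
      rem2 <- s[still] - 0.56 * sqrt(tj[still]) - 0.28 * sqrt(sj[still])
      pg[still] <- clamp(floor((rem2 - t3max) / 0.014), 0, 100)
      t3[still] <- rem2 - 0.014 * pg[still]
    }
  }
  esr <- pmax(round(exp(pmax(t3, 0) / 0.70), 1), 1)
  tibble(tjc28 = as.integer(tj), sjc28 = as.integer(sj), esr = esr,
         pga = as.integer(pg))
}

# Latent DAS28 at a visit: the linear predictor plus a scaled logistic
# error, anchored at the remission cutoff, so that
#   s = 2.6 - 0.35 * (eta - L),  L ~ logistic(0, 1)
# gives P(s < 2.6) = plogis(eta) exactly -- remission follows the stated
# logistic model while disease activity stays continuous and unimodal given
# covariates. Scores are kept a small margin away from the cutoff so that
# integer rounding of components can never flip the endpoint, and clipped to
# a plausible range on the matching side.
draw_visit_scores <- function(eta) {
  s <- 2.6 - 0.35 * (eta - stats::rlogis(length(eta)))
  s <- clamp(s, 0.3, 9.0)
  s[s > 2.6 - 0.07 & s < 2.6] <- 2.6 - 0.07
  s[s >= 2.6 & s < 2.6 + 0.07] <- 2.6 + 0.07
  s
}

#' Simulate a two-cohort study with known ground truth
#'
#' Draws baseline covariates for a trial-like and an observational-like
#' cohort (the latter location-shifted to induce confounding), then draws
#' complete latent DAS28 components at months 6, 12 and 24 such that the
#' marginal log odds ratio of remission between strategies equals
#' `strategy_log_or` at each visit, by numerical calibration over the pooled
#' sample.
#'
#' @param n_trial,n_observational Cohort sizes.
#' @param strategy_log_or,p_remission,outcome_coefs,random_intercept_sd See
#'   [cohort_config()].
#' @param shift_trial,shift_observational Covariate shifts per cohort.
#' @param seed Integer seed; fully determines the output.
#' @return An `eca_study` list: `baseline` (one row per subject), `panel`
#'   (complete long panel, one row per subject-visit) and `truth` (the
#'   recorded marginal log ORs and calibrated model parameters).
#' @export
simulate_study <- function(n_trial = 188, n_observational = 328,
                           strategy_log_or = c(`6` = 0.4, `12` = 0.7, `24` = 0.4),
                           p_remission = c(`6` = 0.35, `12` = 0.45, `24` = 0.55),
                           shift_trial = NULL,
                           shift_observational = eca_default_shift(),
                           outcome_coefs = eca_default_outcome_coefs(),
                           random_intercept_sd = 0.8,
                           seed = 1L) {
  strategy_log_or <- setNames(rep_len(strategy_log_or, 3), eca_visits())
  p_remission <- setNames(rep_len(p_remission, 3), eca_visits())
  if (!all(is.finite(c(strategy_log_or, p_remission,
                       shift_trial %||% 0, shift_observational %||% 0)))) {
    abort("non-finite generator parameters", class = "eca_error_config")
  }
  unknown <- setdiff(c(names(shift_trial), names(shift_observational)),
                     eca_reference_covariates()$name)
  if (length(unknown)) {
    abort(sprintf("unknown covariate in shift: %s", paste(unknown, collapse = ", ")),
          class = "eca_error_config")
  }
  set.seed(substream_seed(seed, "covariates"))
  bl_t <- draw_baseline(n_trial, "trial", shift_trial, "T")
  bl_o <- draw_baseline(n_observational, "observational", shift_observational, "O")
  baseline <- bind_rows(bl_t, bl_o)
  n <- nrow(baseline)

  set.seed(substream_seed(seed, "outcomes"))
  u <- rnorm(n, 0, random_intercept_sd)
  offsets <- baseline_offset(baseline, outcome_coefs, u)
  is_trial <- baseline$cohort == "trial"

  panels <- vector("list", 3)
  calib <- matrix(NA_real_, 3, 2, dimnames = list(eca_visits(), c("alpha", "beta")))
  for (k in seq_along(eca_visits())) {
    v <- eca_visits()[k]
    ab <- calibrate_visit(offsets, p_remission[[k]], strategy_log_or[[k]])
    calib[k, ] <- ab
    eta <- ab[["alpha"]] + ab[["beta"]] * is_trial + offsets
    comp <- score_to_components(draw_visit_scores(eta))
    panels[[k]] <- bind_cols(
      tibble(subject_id = baseline$subject_id, cohort = baseline$cohort,
             visit_month = v),
      comp
    )
  }
  panel <- arrange(bind_rows(panels), .data$subject_id, .data$visit_month)
  structure(
    list(
      baseline = baseline,
      panel = panel,
      truth = list(
        log_or = strategy_log_or,
        p_remission = p_remission,
        calibration = calib,
        outcome_coefs = outcome_coefs,
        random_intercept_sd = random_intercept_sd,
        seed = as.integer(seed)
      )
    ),
    class = "eca_study"
  )
}

#' Generate one cohort's complete latent panel
#'
#' Single-cohort form of [simulate_study()]: calibration is performed on the
#' cohort's own covariate sample, with the strategy coefficient applied when
#' `cohort_id == "trial"`. Two cohorts generated this way with the same
#' `p_remission`/`strategy_log_or` have marginal remission odds differing by
#' the requested log OR.
#'
#' @param config An [cohort_config()] object.
#' @return An `eca_study`-like list with `baseline`, `panel`, `truth`.
#' @export
generate_latent <- function(config) {
  stopifnot(inherits(config, "eca_cohort_config"))
  set.seed(substream_seed(config$seed, "covariates"))
  baseline <- draw_baseline(config$n_subjects, config$cohort_id,
                            config$covariate_shift)
  set.seed(substream_seed(config$seed, "outcomes"))
  u <- rnorm(config$n_subjects, 0, config$random_intercept_sd)
  offsets <- baseline_offset(baseline, config$outcome_coefs, u)
  is_trial <- config$cohort_id == "trial"

  panels <- vector("list", 3)
  calib <- matrix(NA_real_, 3, 2, dimnames = list(eca_visits(), c("alpha", "beta")))
  for (k in seq_along(eca_visits())) {
    ab <- calibrate_visit(offsets, config$p_remission[[k]],
                          config$strategy_log_or[[k]])
    calib[k, ] <- ab
    eta <- ab[["alpha"]] + ab[["beta"]] * is_trial + offsets
    comp <- score_to_components(draw_visit_scores(eta))
    panels[[k]] <- bind_cols(
      tibble(subject_id = baseline$subject_id, cohort = config$cohort_id,
             visit_month = eca_visits()[k]),
      comp
    )
  }
  structure(
    list(
      baseline = baseline,
      panel = arrange(bind_rows(panels), .data$subject_id, .data$visit_month),
      truth = list(log_or = config$strategy_log_or,
                   p_remission = config$p_remission, calibration = calib,
                   seed = config$seed)
    ),
    class = "eca_study"
  )
}

#' @export
print.eca_study <- function(x, ...) {
  cat("Synthetic two-cohort study\n")
  print(count(x$baseline, .data$cohort))
  cat("True marginal log OR (trial vs observational):\n")
  print(x$truth$log_or)
  invisible(x)
}
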
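# Propensity-score IPTW between the two cohorts, with SMD diagnostics.

#' Estimate the propensity of trial-strategy assignment
#'
#' Maximum-likelihood logistic regression of the cohort indicator (trial vs
#' observational) on baseline covariates. Perfect separation is reported as
#' an error naming the offending covariate rather than returning degenerate
#' weights.
#'
#' @param baseline Baseline table (one row per subject) with a `cohort`
#'   column.
#' @param covariates Character vector of covariate columns; defaults to
#'   [eca_covariates()].
#' @return An `eca_propensity` object with the fitted model, per-subject
#'   propensities and a convergence flag. `tidy()` gives coefficients,
#'   `glance()` the fit summary.
#' @export
estimate_propensity <- function(baseline, covariates = eca_covariates()) {
  assert_columns(baseline, c("subject_id", "cohort", covariates), "baseline")
  if (any(!complete.cases(baseline[covariates]))) {
    abort("baseline covariates contain missing values; impute or drop first",
          class = "eca_error_missing_baseline")
  }
  y <- as.numeric(baseline$cohort == "trial")
  dat <- data.frame(.trial = y, baseline[covariates], check.names = FALSE)
  fml <- stats::reformulate(sprintf("`%s`", covariates), response = ".trial")
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    glm(fml, data = dat, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        sep_warn <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  cf <- coef(fit)[-1]
  degenerate <- any(fit$fitted.values < 1e-10 | fit$fitted.values > 1 - 1e-10)
  if (sep_warn || !fit$converged || degenerate) {
    sds <- vapply(baseline[covariates], sd, numeric(1))
    worst <- names(cf)[which.max(abs(cf) * sds)]
    abort(sprintf("propensity model separation involving covariate '%s'", worst),
          class = "eca_error_separation")
  }
  structure(
    list(model = fit, covariates = covariates,
         propensity = setNames(unname(fit$fitted.values), baseline$subject_id),
         assignment = setNames(y, baseline$subject_id),
         converged = fit$converged),
    class = "eca_propensity"
  )
}

#' Inverse probability of treatment weights
#'
#' ATE weights are `1/e(X)` for trial subjects and `1/(1 - e(X))` for
#' observational subjects; stabilization multiplies by the marginal
#' assignment probability so weights average ~1 per arm. Extreme
#' propensities are clipped to percentile bounds before inversion.
#'
#' @param fit An [estimate_propensity()] result.
#' @param estimand `"ATE"` (default, emulating baseline randomization of the
#'   pooled population) or `"ATT"`.
#' @param stabilized Multiply by marginal assignment probabilities.
#' @param truncation Percentile clip for the propensity, default
#'   `c(0.01, 0.99)`; `NULL` disables.
#' @return Tibble `subject_id`, `propensity`, `iptw`.
#' @export
iptw_weights <- function(fit, estimand = c("ATE", "ATT"), stabilized = TRUE,
                         truncation = c(0.01, 0.99)) {
  stopifnot(inherits(fit, "eca_propensity"))
  estimand <- arg_match(estimand)
  e <- fit$propensity
  if (!is.null(truncation)) {
    q <- quantile(e, truncation, names = FALSE)
    e <- clamp(e, q[1], q[2])
  }
  if (any(e <= 0 | e >= 1)) {
    abort("propensity at 0/1 after truncation", class = "eca_error_weights")
  }
  a <- fit$assignment
  p_trial <- mean(a)
  w <- if (estimand == "ATE") {
    ifelse(a == 1, 1 / e, 1 / (1 - e)) *
      (if (stabilized) ifelse(a == 1, p_trial, 1 - p_trial) else 1)
  } else {
    ifelse(a == 1, 1, e / (1 - e)) *
      (if (stabilized) ifelse(a == 1, 1, (1 - p_trial) / p_trial) else 1)
  }
  tibble(subject_id = names(e), propensity = unname(e), iptw = unname(w))
}

#' Standardized mean difference
#'
#' `(m1 - m2) / sqrt((s1^2 + s2^2) / 2)` with optionally weighted group
#' means and variances.
#'
#' @param x Numeric covariate.
#' @param group Two-level grouping (the first sorted unique level is group
#'   1; logical `TRUE` is group 1).
#' @param weights Optional positive weights.
#' @return A single number.
#' @export
smd <- function(x, group, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, length(x))
  g <- if (is.logical(group)) !group else factor(group)
  levs <- if (is.logical(group)) c(FALSE, TRUE) else levels(g)
  if (length(unique(g[!is.na(g)])) != 2) abort("group must have two levels")
  i1 <- g == levs[1]
  m1 <- wmean(x[i1], weights[i1]); v1 <- wvar(x[i1], weights[i1])
  m2 <- wmean(x[!i1], weights[!i1]); v2 <- wvar(x[!i1], weights[!i1])
  pooled <- sqrt((v1 + v2) / 2)
  if (pooled == 0) abort("zero pooled variance", class = "eca_error_variance")
  (m1 - m2) / pooled
}

#' Covariate balance before and after weighting
#'
#' @param baseline Baseline table with `cohort`.
#' @param weights Weight table with `subject_id` and `iptw` (e.g. from
#'   [iptw_weights()]).
#' @param covariates Covariates to diagnose.
#' @return Tibble `covariate`, `smd_unweighted`, `smd_weighted`.
#' @export
balance_table <- function(baseline, weights, covariates = eca_covariates()) {
  assert_columns(weights, c("subject_id", "iptw"), "weights")
  bl <- left_join(baseline, weights, by = "subject_id")
  grp <- bl$cohort == "trial"
  purrr::map_dfr(covariates, function(cv) {
    tibble(
      covariate = cv,
      smd_unweighted = smd(bl[[cv]], grp),
      smd_weighted = smd(bl[[cv]], grp, bl$iptw)
    )
  })
}

#' @export
print.eca_propensity <- function(x, ...) {
  cat(sprintf("Propensity model on %d covariates; propensity range %.3f-%.3f\n",
              length(x$covariates), min(x$propensity), max(x$propensity)))
  invisible(x)
}
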
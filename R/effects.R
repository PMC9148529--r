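# Weighted logistic outcome model, OR/CI transformation and per-arm
# remission proportions.

#' Weighted logistic regression of remission on treatment strategy
#'
#' Fits `remission ~ strategy` with optional weights. Because analysis
#' weights (IPTW, IPCW) are estimated, the default standard error is a
#' robust HC0 sandwich; with constant weights it coincides with the
#' classical 2x2 log-OR standard error, which is also available via
#' `robust = FALSE`.
#'
#' @param data Table with logical/0-1 `remission` and `cohort` (or `arm`)
#'   columns; `"trial"` is the index strategy.
#' @param weights Optional positive weights, one per row.
#' @param robust Use the sandwich variance (default).
#' @return An `eca_fit` list: `beta` (log OR, trial vs observational), `se`,
#'   `n`, plus both variance flavours.
#' @export
fit_outcome_model <- function(data, weights = NULL, robust = TRUE) {
  arm_col <- if ("cohort" %in% names(data)) "cohort" else "arm"
  assert_columns(data, c("remission", arm_col), "outcome data")
  y <- as.numeric(data$remission)
  if (anyNA(y)) abort("missing remission outcomes in analysis set",
                      class = "eca_error_outcome")
  a <- as.numeric(data[[arm_col]] == "trial")
  if (is.null(weights)) weights <- rep(1, length(y))
  if (any(weights <= 0)) abort("weights must be positive")
  for (g in c(0, 1)) {
    yy <- y[a == g]
    if (!length(yy)) abort("empty arm in analysis set", class = "eca_error_outcome")
    if (length(unique(yy)) == 1) {
      abort(sprintf("remission constant in the %s arm: odds ratio undefined",
                    if (g == 1) "trial" else "observational"),
            class = "eca_error_outcome")
    }
  }
  X <- cbind(`(Intercept)` = 1, trial = a)
  fit <- fit_logit(X, y, weights, robust = robust)
  structure(
    list(beta = unname(fit$coefficients[2]),
         se = sqrt(fit$vcov[2, 2]),
         se_classical = sqrt(fit$vcov_classical[2, 2]),
         coefficients = fit$coefficients,
         n = length(y), robust = robust),
    class = "eca_fit"
  )
}

#' Odds ratio with Wald confidence interval
#'
#' Exponentiates a log-OR and its Wald interval; the p-value uses the
#' normal reference, or a t reference when pooled degrees of freedom are
#' supplied.
#'
#' @param beta Log odds ratio(s).
#' @param se Standard error(s), > 0.
#' @param level Confidence level.
#' @param df Degrees of freedom (default `Inf` = normal).
#' @return Tibble `estimate`, `se`, `or`, `ci_low`, `ci_high`, `p`, `df`.
#' @examples
#' or_ci(0.756, 0.288) # OR 2.13, 95% CI 1.21-3.75
#' @export
or_ci <- function(beta, se, level = 0.95, df = Inf) {
  if (any(!is.finite(beta)) || any(se <= 0)) {
    abort("beta must be finite and se > 0", class = "eca_error_input")
  }
  df <- rep_len(df, length(beta))
  q <- ifelse(is.finite(df), qt((1 + level) / 2, df), qnorm((1 + level) / 2))
  z <- beta / se
  p <- ifelse(is.finite(df), 2 * pt(-abs(z), df), 2 * pnorm(-abs(z)))
  tibble(
    estimate = beta, se = se, or = exp(beta),
    ci_low = exp(beta - q * se), ci_high = exp(beta + q * se),
    p = p, df = df
  )
}

#' Weighted remission proportions per strategy arm
#'
#' @param data Table with `remission` and `cohort`/`arm`.
#' @param weights Optional positive weights.
#' @return Tibble `arm`, `n`, `proportion`.
#' @export
remission_proportions <- function(data, weights = NULL) {
  arm_col <- if ("cohort" %in% names(data)) "cohort" else "arm"
  assert_columns(data, c("remission", arm_col), "outcome data")
  if (is.null(weights)) weights <- rep(1, nrow(data))
  tibble(arm = data[[arm_col]], remission = as.numeric(data$remission),
         w = weights) |>
    group_by(.data$arm) |>
    summarise(n = dplyr::n(),
              proportion = wmean(.data$remission, .data$w),
              .groups = "drop")
}

#' @export
print.eca_fit <- function(x, ...) {
  print(or_ci(x$beta, x$se))
  invisible(x)
}
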
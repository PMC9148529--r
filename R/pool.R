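#' Pool per-imputation estimates by Rubin's rules
#'
#' The pooled point estimate is the arithmetic mean of the per-imputation
#' estimates; total variance is the mean within-imputation variance plus
#' `(1 + 1/M)` times the between-imputation variance. Degrees of freedom use
#' the Barnard-Rubin small-sample formula when a complete-data df is
#' supplied. Pooling is intended for the log-OR scale.
#'
#' @param estimates Per-imputation point estimates (length M >= 2).
#' @param variances Per-imputation squared standard errors.
#' @param dfcom Complete-data degrees of freedom (default `Inf`, giving the
#'   large-sample Rubin df).
#' @return An `eca_pool` object: `qbar`, `ubar`, `b`, `t`, `se`, `df`,
#'   `riv`, `lambda`, `m`.
#' @examples
#' rubins_pool(c(0.5, 0.7), c(0.04, 0.04))
#' @export
rubins_pool <- function(estimates, variances, dfcom = Inf) {
  m <- length(estimates)
  if (m < 2 || length(variances) != m) {
    abort("need M >= 2 estimates with matching variances",
          class = "eca_error_pool")
  }
  if (!all(is.finite(estimates)) || !all(is.finite(variances))) {
    abort("non-finite estimates or variances", class = "eca_error_pool")
  }
  qbar <- mean(estimates)
  ubar <- mean(variances)
  b <- var(estimates)
  t <- ubar + (1 + 1 / m) * b
  lambda <- (1 + 1 / m) * b / t
  if (b > 0) {
    df_old <- (m - 1) / lambda^2
    df <- if (is.finite(dfcom)) {
      df_obs <- (dfcom + 1) / (dfcom + 3) * dfcom * (1 - lambda)
      df_old * df_obs / (df_old + df_obs)
    } else {
      df_old
    }
  } else {
    df <- if (is.finite(dfcom)) dfcom else Inf
  }
  structure(
    list(qbar = qbar, ubar = ubar, b = b, t = t, se = sqrt(t), df = df,
         riv = (1 + 1 / m) * b / ubar, lambda = lambda, m = m),
    class = "eca_pool"
  )
}

#' @export
print.eca_pool <- function(x, ...) {
  cat(sprintf("Rubin-pooled estimate %.4f (SE %.4f), M = %d, df = %.1f\n",
              x$qbar, x$se, x$m, x$df))
  invisible(x)
}
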
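# broom-style tidiers for the package's fitted objects.

#' @export
tidy.eca_propensity <- function(x, ...) {
  s <- summary(x$model)$coefficients
  tibble(term = rownames(s), estimate = s[, 1], std.error = s[, 2],
         statistic = s[, 3], p.value = s[, 4])
}

#' @export
glance.eca_propensity <- function(x, ...) {
  tibble(n = length(x$propensity), converged = x$converged,
         propensity_min = min(x$propensity), propensity_max = max(x$propensity))
}

#' @export
tidy.eca_fit <- function(x, ...) {
  bind_cols(tibble(term = "trial"), or_ci(x$beta, x$se))
}

#' @export
glance.eca_fit <- function(x, ...) {
  tibble(n = x$n, robust = x$robust)
}

#' @export
tidy.eca_pool <- function(x, ...) {
  tibble(estimate = x$qbar, std.error = x$se, df = x$df)
}

#' @export
glance.eca_pool <- function(x, ...) {
  tibble(m = x$m, ubar = x$ubar, b = x$b, t = x$t, riv = x$riv,
         lambda = x$lambda, df = x$df)
}

#' @export
tidy.eca_comparison <- function(x, ...) {
  x$effects
}

#' @export
glance.eca_comparison <- function(x, ...) {
  tibble(n_approaches = length(unique(x$effects$approach)),
         visits = paste(x$visits, collapse = "/"),
         m = x$options$m)
}

#' @export
tidy.eca_patterns <- function(x, ...) {
  x$by_visit
}

#' @export
glance.eca_patterns <- function(x, ...) {
  x$summary
}

#' @export
tidy.eca_approach_result <- function(x, ...) {
  x$effects
}
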
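# Internal numerical helpers shared across modules.

# Weighted mean/variance with reliability (frequency-style) weights.
wmean <- function(x, w) sum(w * x) / sum(w)
wvar <- function(x, w) {
  m <- wmean(x, w)
  sum(w * (x - m)^2) / sum(w)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Logistic regression on a prebuilt design matrix; much lighter than the
# formula interface in replicate loops. Returns coefficients, fitted
# probabilities and both classical and HC0 sandwich variances.
fit_logit <- function(X, y, w = NULL, robust = TRUE) {
  if (is.null(w)) w <- rep(1, length(y))
  fit <- suppressWarnings(
    glm.fit(X, y, weights = w, family = quasibinomial())
  )
  p <- fit$fitted.values
  beta <- fit$coefficients
  info <- crossprod(X, X * (w * p * (1 - p)))
  bread <- tryCatch(solve(info), error = function(e) NULL)
  if (is.null(bread)) {
    abort("outcome model information matrix is singular", class = "eca_error_fit")
  }
  vc_classical <- bread
  vc <- vc_classical
  if (robust) {
    sc <- X * (w * (y - p))
    vc <- bread %*% crossprod(sc) %*% bread
  }
  list(
    coefficients = beta,
    fitted = p,
    vcov = vc,
    vcov_classical = vc_classical,
    converged = fit$converged
  )
}

# Pool a vector of per-imputation proportions on the logit scale.
pool_proportions <- function(p, eps = 1e-6) {
  p <- clamp(p, eps, 1 - eps)
  plogis(mean(qlogis(p)))
}

# Stable per-stage seeds derived from one global seed (kept well below 2^31).
substream_seed <- function(seed, stage) {
  offsets <- c(
    covariates = 11L, outcomes = 23L, missingness = 37L, imputation = 53L,
    analysis = 71L, bootstrap = 89L
  )
  off <- offsets[[stage]]
  as.integer((as.numeric(seed) * 7919 + off * 104729) %% 2147483629)
}

assert_columns <- function(df, cols, what = "table") {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort(
      sprintf("%s is missing column(s): %s", what, paste(missing, collapse = ", ")),
      class = "eca_error_schema"
    )
  }
  invisible(df)
}
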
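# Multiple imputation by chained equations with predictive mean matching.
#
# The variables to be imputed (TJC28, SJC28, ESR, PGA at months 6/12/24)
# have limited ranges and skewed distributions, so every conditional draw
# uses Bayesian-linear-regression predictive mean matching: donors are
# actual observed values, which keeps joint counts integral and all
# components in their legal ranges without post-hoc clipping. Models are
# fitted separately per cohort and the completed panels concatenated.
#
# One chained run imputes *every* missing cell; an approach's scope
# (missing-at-visit only / + intermittent / + drop-out) is applied as a
# retention mask at completion time. Cells outside the scope revert to
# missing in the completed panels, so approaches with nested scopes share
# identical conditional models and draws by construction.

#' Imputation plan
#'
#' @param m Number of imputed datasets (>= 2, default 10).
#' @param n_iterations Chained-equation sweeps per imputation (default 10).
#' @param method Conditional draw: `"pmm"` (default; donors are observed
#'   values, respecting ranges and integrality) or `"norm"` (Bayesian
#'   linear-regression draws, clipped and rounded to legal ranges; preferable
#'   when selection pushes recipients outside the observed donor support,
#'   where matching cannot extrapolate).
#' @param pmm_k Predictive-mean-matching donor pool size.
#' @param predictors Baseline columns entering every conditional model (in
#'   addition to the other visit components).
#' @param delta MNAR sensitivity shift, on the DAS28 scale, added to imputed
#'   (never observed) outcomes; applied through the inflammatory component
#'   so the implied score shifts by exactly `delta`. 0 reproduces MAR.
#' @param seed Integer seed for the imputation draws.
#' @return An `eca_mice_plan` list.
#' @export
mice_plan <- function(m = 10, n_iterations = 10, method = c("pmm", "norm"),
                      pmm_k = 5, predictors = eca_covariates(), delta = 0,
                      seed = 1L) {
  if (m < 2) abort("m must be >= 2", class = "eca_error_plan")
  method <- arg_match(method)
  structure(
    list(m = as.integer(m), n_iterations = as.integer(n_iterations),
         method = method, pmm_k = as.integer(pmm_k), predictors = predictors,
         delta = delta, seed = as.integer(seed)),
    class = "eca_mice_plan"
  )
}

# Legal ranges for clipping/rounding "norm" draws per component.
component_bounds <- function(col) {
  comp <- sub("_[0-9]+$", "", col)
  switch(comp,
    tjc28 = , sjc28 = list(lo = 0, hi = 28, digits = 0),
    esr = list(lo = 1, hi = Inf, digits = 1),
    pga = list(lo = 0, hi = 100, digits = 0)
  )
}

#' Chained-equations multiple imputation of visit components
#'
#' @param panel Schedule-aligned long panel with `NA` holes.
#' @param baseline Complete baseline table.
#' @param plan An [mice_plan()].
#' @return An `eca_imputations` object holding `m` completed copies;
#'   observed cells are identical across copies and to the input. Use
#'   [imputed_panels()] to materialise completed long panels under a scope.
#' @export
mice_impute <- function(panel, baseline, plan = mice_plan()) {
  stopifnot(inherits(plan, "eca_mice_plan"))
  assert_columns(panel, c("subject_id", "visit_month", eca_components()), "panel")
  visits <- eca_visits()
  cohorts <- if ("cohort" %in% names(panel)) unique(panel$cohort) else "all"
  set.seed(substream_seed(plan$seed, "imputation"))
  runs <- lapply(cohorts, function(ch) {
    rows <- if ("cohort" %in% names(panel)) panel$cohort == ch else TRUE
    impute_one_cohort(panel[rows, , drop = FALSE],
                      baseline[baseline$subject_id %in% panel$subject_id[rows], ,
                               drop = FALSE],
                      plan)
  })
  names(runs) <- cohorts
  structure(
    list(runs = runs, plan = plan, panel = panel,
         chain_means = lapply(runs, `[[`, "chain_means")),
    class = "eca_imputations"
  )
}

# Wide layout: one row per subject, 12 visit-component columns, so later
# visits inform earlier gaps and vice versa.
panel_to_wide <- function(panel) {
  visits <- eca_visits()
  subjects <- unique(panel$subject_id)
  Y <- matrix(NA_real_, length(subjects), 4L * length(visits))
  cn <- as.vector(outer(eca_components(), visits, paste, sep = "_"))
  colnames(Y) <- cn
  ri <- match(panel$subject_id, subjects)
  ci <- match(panel$visit_month, visits)
  for (j in seq_along(eca_components())) {
    Y[cbind(ri, (ci - 1L) * 4L + j)] <- panel[[eca_components()[j]]]
  }
  list(Y = Y, subjects = subjects)
}

impute_one_cohort <- function(panel, baseline, plan) {
  w <- panel_to_wide(panel)
  Y <- w$Y
  miss <- is.na(Y)
  if (!any(miss)) {
    return(list(Y = replicate(plan$m, Y, simplify = FALSE),
                mask = miss, subjects = w$subjects, chain_means = NULL))
  }
  zero_obs <- colSums(!miss) == 0
  if (any(zero_obs)) {
    abort(sprintf("no observed values to impute from: %s",
                  paste(colnames(Y)[zero_obs], collapse = ", ")),
          class = "eca_error_impute")
  }
  bl <- baseline[match(w$subjects, baseline$subject_id), , drop = FALSE]
  XB <- as.matrix(bl[, plan$predictors, drop = FALSE])
  storage.mode(XB) <- "double"
  # skewed inflammatory markers enter conditional models on the log scale
  for (nm in intersect(c("esr_0", "crp_0", "symptom_dur"), colnames(XB))) {
    XB[, nm] <- log(pmax(XB[, nm], 0.1))
  }
  # impute in increasing-missingness order, ties by visit then component
  frac <- colMeans(miss)
  ord <- order(frac, seq_len(ncol(Y)))
  ord <- ord[frac[ord] > 0]

  chain_means <- array(NA_real_, c(plan$m, plan$n_iterations, length(ord)),
                       dimnames = list(NULL, NULL, colnames(Y)[ord]))
  out <- vector("list", plan$m)
  for (m in seq_len(plan$m)) {
    Ym <- Y
    for (j in which(frac > 0)) { # initial fill: draws from the observed margin
      Ym[miss[, j], j] <- sample(Y[!miss[, j], j], sum(miss[, j]), replace = TRUE)
    }
    for (it in seq_len(plan$n_iterations)) {
      for (jj in seq_along(ord)) {
        j <- ord[jj]
        obs <- !miss[, j]
        D <- cbind(1, XB, Ym[, -j, drop = FALSE])
        drawn <- impute_draw(D[obs, , drop = FALSE], Y[obs, j],
                             D[!obs, , drop = FALSE], plan,
                             colnames(Y)[j])
        Ym[!obs, j] <- drawn
        chain_means[m, it, jj] <- mean(drawn)
      }
    }
    if (plan$delta != 0) { # DAS28-scale delta through the ln(ESR) term
      for (v in eca_visits()) {
        cl <- paste0("esr_", v)
        i <- miss[, cl]
        Ym[i, cl] <- pmax(Ym[i, cl] * exp(plan$delta / .das28_coefs[["esr"]]), 1)
      }
    }
    out[[m]] <- Ym
  }
  list(Y = out, mask = miss, subjects = w$subjects, chain_means = chain_means)
}

# One chained-equation draw: posterior draw of (beta, sigma) from the
# observed-data Bayesian linear regression, then either predictive mean
# matching (donors among the k nearest predictive means) or a clipped
# normal predictive draw.
impute_draw <- function(Do, yo, Dm, plan, col) {
  p <- ncol(Do)
  xtx <- crossprod(Do)
  xty <- crossprod(Do, yo)
  R <- tryCatch(chol(xtx), error = function(e) {
    # near-collinear design: tiny ridge keeps the posterior draw proper
    chol(xtx + diag(1e-8 * (diag(xtx) + 1), p))
  })
  beta_hat <- backsolve(R, forwardsolve(t(R), xty))
  res <- yo - drop(Do %*% beta_hat)
  df <- max(length(yo) - p, 1)
  sigma2 <- sum(res^2) / rchisq(1, df)
  beta_star <- beta_hat + backsolve(R, rnorm(p)) * sqrt(sigma2)
  pred_mis <- drop(Dm %*% beta_star)
  if (plan$method == "pmm") {
    pred_obs <- drop(Do %*% beta_hat)
    match_pmm(pred_obs, yo, pred_mis, plan$pmm_k)
  } else {
    b <- component_bounds(col)
    round(clamp(pred_mis + rnorm(length(pred_mis), 0, sqrt(sigma2)),
                b$lo, b$hi), b$digits)
  }
}

match_pmm <- function(pred_obs, yo, pred_mis, k) {
  o <- order(pred_obs)
  po <- pred_obs[o]
  yo_s <- yo[o]
  n <- length(po)
  k <- min(k, n)
  nm <- length(pred_mis)
  pos <- findInterval(pred_mis, po)
  # candidate window of 2k sorted positions always contains the k nearest
  ci <- outer(pos, seq.int(-k + 1L, k), `+`)
  ci[ci < 1L] <- 1L
  ci[ci > n] <- n
  d <- abs(matrix(po[ci], nm) - pred_mis)
  # take the r-th nearest with r uniform on 1..k (random donor among k)
  r <- sample.int(k, nm, replace = TRUE)
  sel <- integer(nm)
  rows <- seq_len(nm)
  for (s in seq_len(k)) {
    j <- max.col(-d, ties.method = "first")
    hit <- r == s
    sel[hit] <- j[hit]
    if (s < k) d[cbind(rows, j)] <- Inf
  }
  yo_s[ci[cbind(rows, sel)]]
}

#' Materialise completed panels under a missingness scope
#'
#' @param imputations An [mice_impute()] result.
#' @param scope Which ground-truth missingness types to complete:
#'   `"all"` (default), `"missing_at_visit"` (components at recorded visits
#'   only) or `"missing_at_visit+intermittent"`. Requires `labels` for any
#'   scope other than `"all"`. Cells outside the scope revert to missing.
#' @param labels Label table (ground truth or classifier output).
#' @return A list of `m` completed long panels (tibbles).
#' @export
imputed_panels <- function(imputations,
                           scope = c("all", "missing_at_visit",
                                     "missing_at_visit+intermittent"),
                           labels = NULL) {
  stopifnot(inherits(imputations, "eca_imputations"))
  scope <- arg_match(scope)
  panel <- imputations$panel
  visits <- eca_visits()
  keep_types <- switch(scope,
    all = eca_labels()[-1],
    missing_at_visit = "missing_at_visit",
    `missing_at_visit+intermittent` = c("missing_at_visit", "intermittent")
  )
  if (scope != "all" && is.null(labels)) {
    abort("labels are required for a restricted scope")
  }
  lapply(seq_len(imputations$plan$m), function(m) {
    out <- panel
    for (ch in names(imputations$runs)) {
      run <- imputations$runs[[ch]]
      Ym <- run$Y[[m]]
      ri_panel <- which(if ("cohort" %in% names(panel)) panel$cohort == ch else TRUE)
      sub <- panel[ri_panel, ]
      rw <- match(sub$subject_id, run$subjects)
      cw <- (match(sub$visit_month, visits) - 1L) * 4L
      for (j in seq_along(eca_components())) {
        nm <- eca_components()[j]
        vals <- Ym[cbind(rw, cw + j)]
        # PMM donors are observed values, so integer columns stay integral
        if (is.integer(out[[nm]])) vals <- as.integer(round(vals))
        fill <- is.na(sub[[nm]])
        out[[nm]][ri_panel[fill]] <- vals[fill]
      }
    }
    if (scope != "all") { # revert out-of-scope cells to missing
      lab <- labels[match(paste(out$subject_id, out$visit_month),
                          paste(labels$subject_id, labels$visit_month)), ]
      revert <- !(as.character(lab$label) %in% c("observed", keep_types))
      was_na <- is.na(panel[, eca_components()])
      for (j in seq_along(eca_components())) {
        nm <- eca_components()[j]
        i <- revert & was_na[, j]
        out[[nm]][i] <- NA
      }
    }
    out
  })
}

#' @export
print.eca_imputations <- function(x, ...) {
  n_miss <- sum(vapply(x$runs, function(r) sum(r$mask), numeric(1)))
  cat(sprintf("Chained-equations imputation: m = %d, %d sweeps, %d missing cells\n",
              x$plan$m, x$plan$n_iterations, n_miss))
  invisible(x)
}
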
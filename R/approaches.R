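# End-to-end dispatch of the five missing-data approaches.

#' The five approach identifiers
#' @return Character vector.
#' @export
eca_approaches <- function() {
  c("complete_case", "strict_censor_ipcw", "mi_censor_ipcw", "mi_ipcw", "mi_all")
}

#' Analysis options
#'
#' @param covariates Propensity/imputation baseline covariates.
#' @param ipcw_predictors Censoring-model predictors (baseline columns plus
#'   `"das28_0"`, `"das28_last"`).
#' @param estimand,stabilize_iptw,iptw_truncation IPTW settings, see
#'   [iptw_weights()].
#' @param stabilize_ipcw,ipcw_truncation IPCW settings, see [ipcw_weights()].
#' @param m,n_iterations,mice_method,pmm_k,delta Imputation settings, see
#'   [mice_plan()].
#' @param robust Sandwich standard errors in the outcome model.
#' @param level Confidence level.
#' @param by_cohort_censoring Fit censoring models per cohort.
#' @param min_at_risk Smallest admissible censoring-model risk set.
#' @param share_imputations Reuse one impute-all chained run across the MI
#'   approaches (exact under the scope-as-mask definition).
#' @param iptw_within_imputation Re-estimate the propensity model inside
#'   each imputed dataset (equivalent to the default when baselines are
#'   complete).
#' @param seed Seed for the imputation draws.
#' @return An `eca_options` list.
#' @export
analysis_options <- function(covariates = eca_covariates(),
                             ipcw_predictors = c("das28_0", "age", "das28_last"),
                             estimand = "ATE",
                             stabilize_iptw = TRUE,
                             iptw_truncation = c(0.01, 0.99),
                             stabilize_ipcw = TRUE,
                             ipcw_truncation = NULL,
                             m = 10, n_iterations = 10, mice_method = "pmm",
                             pmm_k = 5, delta = 0,
                             robust = TRUE, level = 0.95,
                             by_cohort_censoring = TRUE, min_at_risk = 20,
                             share_imputations = TRUE,
                             iptw_within_imputation = FALSE,
                             seed = 1L) {
  structure(as.list(environment()), class = "eca_options")
}

compute_iptw <- function(data, opts) {
  fit <- estimate_propensity(data$baseline, opts$covariates)
  iptw_weights(fit, estimand = opts$estimand, stabilized = opts$stabilize_iptw,
               truncation = opts$iptw_truncation)
}

default_plan <- function(opts) {
  mice_plan(m = opts$m, n_iterations = opts$n_iterations,
            method = opts$mice_method, pmm_k = opts$pmm_k,
            predictors = opts$covariates, delta = opts$delta, seed = opts$seed)
}

#' Run one missing-data approach end to end
#'
#' Dispatches per the approach definition: complete follow-up case analysis
#' (exclusion of any subject without all three visits observed), strict
#' censoring + IPCW, MI + censoring + IPCW (impute missing-at-visit, censor
#' at the first intermittent visit), MI + IPCW (impute missing-at-visit and
#' intermittent, weight for natural drop-out) and MI for all. Every
#' approach's outcome model is IPTW-weighted; MI approaches refit the
#' censoring models within each imputed dataset and pool the final log ORs
#' by Rubin's rules.
#'
#' @param approach One of [eca_approaches()].
#' @param data An `eca_observed` object (or a list with `panel`, `labels`,
#'   `baseline`).
#' @param options An [analysis_options()].
#' @param visits Analysis visits (default all three).
#' @param iptw Optional precomputed [iptw_weights()] table.
#' @param imputations Optional precomputed [mice_impute()] result.
#' @return An `eca_approach_result` with `effects` (one row per visit),
#'   `proportions` and `diagnostics`.
#' @export
run_approach <- function(approach, data, options = analysis_options(),
                         visits = eca_visits(), iptw = NULL,
                         imputations = NULL) {
  approach <- arg_match(approach, eca_approaches())
  opts <- options
  if (is.null(iptw)) iptw <- compute_iptw(data, opts)
  w_iptw <- setNames(iptw$iptw, iptw$subject_id)
  res <- tryCatch(
    switch(approach,
      complete_case = run_complete_case(data, w_iptw, opts, visits),
      strict_censor_ipcw = run_weighted(data, w_iptw, opts, visits,
                                        rule = "strict"),
      mi_censor_ipcw = run_mi(data, w_iptw, opts, visits, imputations,
                              scope = "missing_at_visit",
                              rule = "intermittent_only"),
      mi_ipcw = run_mi(data, w_iptw, opts, visits, imputations,
                       scope = "missing_at_visit+intermittent",
                       rule = "dropout_only"),
      mi_all = run_mi(data, w_iptw, opts, visits, imputations,
                      scope = "all", rule = NULL)
    ),
    error = function(e) {
      abort(sprintf("approach '%s' failed: %s", approach, conditionMessage(e)),
            class = "eca_error_approach", parent = e)
    }
  )
  res$effects <- mutate(res$effects, approach = approach, .before = 1)
  res$proportions <- mutate(res$proportions, approach = approach, .before = 1)
  structure(c(res, list(approach = approach)), class = "eca_approach_result")
}

# Per-visit weighted fit on one completed/censored analysis panel.
visit_fits <- function(panel_sc, weights_tbl, w_iptw, opts, visits) {
  purrr::map(visits, function(v) {
    rows <- filter(panel_sc, .data$visit_month == v)
    if (!is.null(weights_tbl)) {
      wv <- filter(weights_tbl, .data$visit_month == v)
      rows <- filter(rows, .data$subject_id %in% wv$subject_id)
      w <- w_iptw[rows$subject_id] *
        wv$ipcw[match(rows$subject_id, wv$subject_id)]
    } else {
      rows <- filter(rows, !is.na(.data$remission))
      w <- w_iptw[rows$subject_id]
    }
    fit <- fit_outcome_model(rows, w, robust = opts$robust)
    props <- remission_proportions(rows, w)
    list(fit = fit, props = props, n = nrow(rows),
         w_quantiles = quantile(w, c(0, 0.5, 0.95, 1), names = FALSE),
         ess = sum(w)^2 / sum(w^2))
  })
}

collect_single <- function(fits, visits, opts) {
  effects <- purrr::map2_dfr(fits, visits, function(f, v) {
    bind_cols(tibble(visit_month = v, n = f$n),
              or_ci(f$fit$beta, f$fit$se, level = opts$level))
  })
  proportions <- purrr::map2_dfr(fits, visits, function(f, v) {
    mutate(f$props, visit_month = v, .before = 1)
  })
  diagnostics <- purrr::map2_dfr(fits, visits, function(f, v) {
    tibble(visit_month = v, n = f$n, ess = f$ess,
           w_min = f$w_quantiles[1], w_median = f$w_quantiles[2],
           w_p95 = f$w_quantiles[3], w_max = f$w_quantiles[4])
  })
  list(effects = effects, proportions = proportions, diagnostics = diagnostics)
}

run_complete_case <- function(data, w_iptw, opts, visits) {
  complete_ids <- data$labels |>
    group_by(.data$subject_id) |>
    summarise(complete = all(.data$label == "observed"), .groups = "drop") |>
    filter(.data$complete) |>
    pull(.data$subject_id)
  if (!length(complete_ids)) {
    abort("no subjects with complete follow-up", class = "eca_error_empty")
  }
  panel_sc <- add_das28(filter(data$panel, .data$subject_id %in% complete_ids))
  fits <- visit_fits(panel_sc, NULL, w_iptw, opts, visits)
  collect_single(fits, visits, opts)
}

run_weighted <- function(data, w_iptw, opts, visits, rule) {
  cens <- artificial_censor(data$panel, data$labels, rule)
  models <- fit_censoring_models(cens, data$baseline,
                                 predictors = opts$ipcw_predictors,
                                 by_cohort = opts$by_cohort_censoring,
                                 min_at_risk = opts$min_at_risk)
  wts <- ipcw_weights(models, stabilized = opts$stabilize_ipcw,
                      truncation = opts$ipcw_truncation)
  panel_sc <- add_das28(cens$panel)
  fits <- visit_fits(panel_sc, wts, w_iptw, opts, visits)
  collect_single(fits, visits, opts)
}

run_mi <- function(data, w_iptw, opts, visits, imputations, scope, rule) {
  if (is.null(imputations)) {
    imputations <- mice_impute(data$panel, data$baseline, default_plan(opts))
  }
  panels <- imputed_panels(imputations, scope = scope, labels = data$labels)
  per_m <- purrr::map(panels, function(pm) {
    if (opts$iptw_within_imputation) {
      wtbl <- compute_iptw(data, opts)
      w_iptw <- setNames(wtbl$iptw, wtbl$subject_id)
    }
    if (!is.null(rule)) {
      cens <- artificial_censor(pm, data$labels, rule)
      models <- fit_censoring_models(cens, data$baseline,
                                     predictors = opts$ipcw_predictors,
                                     by_cohort = opts$by_cohort_censoring,
                                     min_at_risk = opts$min_at_risk)
      wts <- ipcw_weights(models, stabilized = opts$stabilize_ipcw,
                          truncation = opts$ipcw_truncation)
      visit_fits(add_das28(cens$panel), wts, w_iptw, opts, visits)
    } else {
      visit_fits(add_das28(pm), NULL, w_iptw, opts, visits)
    }
  })
  effects <- purrr::map_dfr(seq_along(visits), function(k) {
    betas <- map_dbl(per_m, ~ .x[[k]]$fit$beta)
    vars <- map_dbl(per_m, ~ .x[[k]]$fit$se^2)
    n_k <- per_m[[1]][[k]]$n
    rp <- rubins_pool(betas, vars, dfcom = n_k - 2)
    bind_cols(tibble(visit_month = visits[k], n = n_k),
              or_ci(rp$qbar, rp$se, level = opts$level, df = rp$df))
  })
  proportions <- purrr::map_dfr(seq_along(visits), function(k) {
    purrr::map_dfr(per_m, ~ .x[[k]]$props) |>
      group_by(.data$arm) |>
      summarise(n = .data$n[1],
                proportion = pool_proportions(.data$proportion),
                .groups = "drop") |>
      mutate(visit_month = visits[k], .before = 1)
  })
  diagnostics <- purrr::map_dfr(seq_along(visits), function(k) {
    tibble(visit_month = visits[k], n = per_m[[1]][[k]]$n,
           ess = mean(map_dbl(per_m, ~ .x[[k]]$ess)),
           w_min = NA_real_, w_median = NA_real_, w_p95 = NA_real_,
           w_max = NA_real_, m = length(per_m))
  })
  list(effects = effects, proportions = proportions, diagnostics = diagnostics)
}

#' Compare all approaches on one two-cohort panel
#'
#' Runs the requested approaches with one shared propensity fit (baselines
#' are complete in the synthetic path) and, by default, one shared
#' chained-equations run, and binds the per-visit effect estimates into a
#' five-approaches-by-three-visits report, together with the per-arm
#' estimated remission proportions.
#'
#' @inheritParams run_approach
#' @param approaches Subset of [eca_approaches()].
#' @return An `eca_comparison`: `effects`, `proportions`, `diagnostics`,
#'   `iptw`, plus the generator `truth` when present. `tidy()` returns the
#'   effects table.
#' @export
compare_approaches <- function(data, approaches = eca_approaches(),
                               options = analysis_options(),
                               visits = eca_visits()) {
  approaches <- match.arg(approaches, eca_approaches(), several.ok = TRUE)
  iptw <- compute_iptw(data, options)
  imputations <- NULL
  if (options$share_imputations &&
      any(approaches %in% c("mi_censor_ipcw", "mi_ipcw", "mi_all"))) {
    imputations <- mice_impute(data$panel, data$baseline, default_plan(options))
  }
  results <- purrr::map(approaches, function(ap) {
    run_approach(ap, data, options, visits, iptw = iptw,
                 imputations = imputations)
  })
  names(results) <- approaches
  structure(
    list(
      effects = purrr::map_dfr(results, "effects"),
      proportions = purrr::map_dfr(results, "proportions"),
      diagnostics = purrr::map_dfr(results, "diagnostics", .id = "approach"),
      iptw = iptw,
      truth = data$truth,
      options = options,
      visits = visits
    ),
    class = "eca_comparison"
  )
}

#' @export
print.eca_comparison <- function(x, digits = 3, ...) {
  cat("Approach comparison (log OR of remission, trial vs observational)\n")
  out <- mutate(
    x$effects,
    dplyr::across(c("estimate", "se"), ~ round(.x, 3)),
    dplyr::across(c("or", "ci_low", "ci_high"), ~ round(.x, 2)),
    p = signif(.data$p, 2)
  )
  print(select(out, -"df"), n = Inf)
  invisible(x)
}
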
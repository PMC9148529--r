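# Artificial censoring to a monotone pattern, sequential censoring-hazard
# models, and cumulative inverse probability of censoring weights.

#' Censor a panel to a monotone missingness pattern
#'
#' Each subject is censored at the first visit whose label falls in the
#' rule's event set; all data at and after that visit are blanked, so the
#' output always has a monotone pattern. Naturally occurring drop-out is
#' always a censoring event (it is precisely what IPCW reweights for); the
#' rule controls which *additional* non-monotone events are converted to
#' drop-out:
#'
#' * `"strict"`: first visit with missing outcome data or first intermittent
#'   missing visit, whichever comes first (pre-imputation use).
#' * `"intermittent_only"`: first intermittent visit (use after MI has
#'   filled missing-at-visit components).
#' * `"dropout_only"`: no artificial events (use after MI has filled both
#'   missing-at-visit and intermittent gaps).
#'
#' @param panel Schedule-aligned long panel.
#' @param labels Label table consistent with the panel (ground truth or
#'   [classify_missingness()] output).
#' @param rule Censoring rule, see above.
#' @return An `eca_censored` list: the blanked `panel` and a `censor_table`
#'   (`subject_id`, `cohort`, `censor_visit`; `NA` = never censored).
#' @export
artificial_censor <- function(panel, labels,
                              rule = c("strict", "intermittent_only", "dropout_only")) {
  rule <- arg_match(rule)
  events <- switch(rule,
    strict = c("missing_at_visit", "intermittent", "dropout"),
    intermittent_only = c("intermittent", "dropout"),
    dropout_only = "dropout"
  )
  assert_columns(labels, c("subject_id", "visit_month", "label"), "labels")
  visits <- eca_visits()
  lab <- arrange(labels, .data$subject_id, .data$visit_month)
  subjects <- unique(lab$subject_id)
  ev <- matrix(lab$label %in% events, length(subjects), length(visits),
               byrow = TRUE)
  # earliest TRUE column per row (first event visit)
  first <- max.col(ev * matrix(rev(seq_along(visits)), length(subjects),
                               length(visits), byrow = TRUE),
                   ties.method = "first")
  cens <- tibble(
    subject_id = subjects,
    censor_visit = ifelse(rowSums(ev) > 0, visits[first], NA_real_)
  )
  if ("cohort" %in% names(labels)) {
    cens <- left_join(cens, distinct(labels, .data$subject_id, .data$cohort),
                      by = "subject_id") |>
      select("subject_id", "cohort", "censor_visit")
  }
  out <- left_join(panel, select(cens, "subject_id", "censor_visit"),
                   by = "subject_id")
  blank <- !is.na(out$censor_visit) & out$visit_month >= out$censor_visit
  for (nm in eca_components()) out[[nm]][blank] <- NA
  out$censor_visit <- NULL
  structure(list(panel = out, censor_table = cens, rule = rule),
            class = "eca_censored")
}

#' Sequential censoring-hazard models
#'
#' One logistic model per visit for the probability of becoming unavailable
#' at that visit given still available before it, using baseline covariates
#' and the last observed DAS28 (last observation carried forward; baseline
#' DAS28 before month 6). Models are fitted separately per cohort by
#' default, since the two cohorts' missingness processes differ by design.
#'
#' @param censored An [artificial_censor()] result.
#' @param baseline Baseline table.
#' @param predictors Predictor names: baseline columns plus the special
#'   names `"das28_0"` and `"das28_last"`.
#' @param by_cohort Fit per cohort (default) or pooled.
#' @param min_at_risk Smallest admissible risk set per model.
#' @return An `eca_ipcw_models` object: per-visit fitted hazards for at-risk
#'   subjects and marginal hazards.
#' @export
fit_censoring_models <- function(censored, baseline,
                                 predictors = c("das28_0", "age", "das28_last"),
                                 by_cohort = TRUE, min_at_risk = 20) {
  stopifnot(inherits(censored, "eca_censored"))
  visits <- eca_visits()
  cens <- censored$censor_table
  # fail loudly if the input is not monotone: no data may remain at or
  # after a subject's censoring visit
  cv <- cens$censor_visit[match(censored$panel$subject_id, cens$subject_id)]
  after <- !is.na(cv) & censored$panel$visit_month >= cv
  if (any(after & rowSums(!is.na(censored$panel[, eca_components()])) > 0)) {
    abort("censored panel is not monotone: data present after the censoring visit",
          class = "eca_error_monotone")
  }
  # last observed DAS28 carried forward from the censored panel
  sc <- add_das28(censored$panel)
  wide <- tidyr::pivot_wider(select(sc, "subject_id", "visit_month", "das28"),
                             names_from = "visit_month", values_from = "das28")
  wide <- wide[match(cens$subject_id, wide$subject_id), ]
  bl <- baseline[match(cens$subject_id, baseline$subject_id), ]

  groups <- if (by_cohort) split(seq_len(nrow(cens)), cens$cohort)
            else list(all = seq_len(nrow(cens)))
  hazards <- list()
  marginal <- list()
  models <- list()
  for (g in names(groups)) {
    idx <- groups[[g]]
    for (k in seq_along(visits)) {
      v <- visits[k]
      at_risk <- idx[is.na(cens$censor_visit[idx]) | cens$censor_visit[idx] >= v]
      if (length(at_risk) < min_at_risk) {
        abort(sprintf("risk set at visit %d in cohort %s has only %d subjects",
                      v, g, length(at_risk)),
              class = "eca_error_risk_set")
      }
      event <- as.numeric(!is.na(cens$censor_visit[at_risk]) &
                            cens$censor_visit[at_risk] == v)
      if (sum(event) == 0) {
        h <- rep(0, length(at_risk))
        models[[paste(g, v)]] <- NULL
      } else {
        das_last <- bl$das28_0[at_risk]
        if (k > 1) { # most recent available prior DAS28, baseline as fallback
          for (j in seq_len(k - 1)) {
            prior <- wide[[as.character(visits[j])]][at_risk]
            das_last <- ifelse(is.na(prior), das_last, prior)
          }
        }
        X <- matrix(1, length(at_risk), 1L)
        for (nm in predictors) {
          col <- switch(nm,
            das28_0 = bl$das28_0[at_risk],
            das28_last = das_last,
            bl[[nm]][at_risk] %||% abort(sprintf("unknown predictor: %s", nm))
          )
          X <- cbind(X, col)
        }
        colnames(X) <- c("(Intercept)", predictors)
        # drop aliased columns (e.g. das28_last == das28_0 before month 6)
        qx <- qr(X)
        if (qx$rank < ncol(X)) X <- X[, qx$pivot[seq_len(qx$rank)], drop = FALSE]
        mfit <- fit_logit(X, event, robust = FALSE)
        degenerate <- any(mfit$fitted < 1e-10 | mfit$fitted > 1 - 1e-10)
        if (degenerate || !mfit$converged) {
          sds <- c(1, apply(X[, -1, drop = FALSE], 2, sd))
          worst <- colnames(X)[which.max(abs(mfit$coefficients) * sds)]
          abort(sprintf("censoring model separation at visit %d (%s), covariate '%s'",
                        v, g, worst),
                class = "eca_error_separation")
        }
        h <- mfit$fitted
        models[[paste(g, v)]] <- mfit$coefficients
      }
      hazards[[paste(g, v)]] <- tibble(
        subject_id = cens$subject_id[at_risk], cohort = g,
        visit_month = v, hazard = h, event = event
      )
      marginal[[paste(g, v)]] <- tibble(cohort = g, visit_month = v,
                                        marginal_hazard = mean(event))
    }
  }
  structure(
    list(hazards = bind_rows(hazards), marginal = bind_rows(marginal),
         models = models, censor_table = cens, by_cohort = by_cohort,
         predictors = predictors),
    class = "eca_ipcw_models"
  )
}

#' Cumulative inverse probability of censoring weights
#'
#' For a subject still available at visit `k`, the unstabilized weight is
#' the inverse product of their fitted probabilities of remaining
#' uncensored through `k`; stabilization multiplies by the same product of
#' marginal hazards, so weights average ~1. Weights are only defined up to a
#' censored subject's last available visit.
#'
#' @param models A [fit_censoring_models()] result.
#' @param stabilized Use marginal-hazard numerators (default).
#' @param truncation Optional percentile clip `c(lo, hi)` of the final
#'   weights per visit; `NULL` (default) disables.
#' @return Tibble `subject_id`, `visit_month`, `ipcw`.
#' @export
ipcw_weights <- function(models, stabilized = TRUE, truncation = NULL) {
  stopifnot(inherits(models, "eca_ipcw_models"))
  h <- models$hazards
  if (any(h$hazard >= 1 & h$event == 0)) {
    abort("fitted censoring hazard of 1 for an uncensored subject",
          class = "eca_error_weights")
  }
  h <- left_join(h, models$marginal, by = c("cohort", "visit_month"))
  visits <- eca_visits()
  subjects <- unique(h$subject_id)
  si <- match(h$subject_id, subjects)
  vi <- match(h$visit_month, visits)
  term <- avail <- matrix(NA_real_, length(subjects), length(visits))
  term[cbind(si, vi)] <- (if (stabilized) 1 - h$marginal_hazard else 1) /
    (1 - h$hazard)
  avail[cbind(si, vi)] <- 1 - h$event
  # at-risk sets are prefixes per subject, so a running product per column
  # is the cumulative weight through each visit
  for (j in seq_along(visits)[-1]) term[, j] <- term[, j] * term[, j - 1]
  keep <- which(!is.na(term) & avail == 1) # available at the visit
  w <- tibble(
    subject_id = subjects[(keep - 1L) %% length(subjects) + 1L],
    visit_month = visits[(keep - 1L) %/% length(subjects) + 1L],
    ipcw = term[keep]
  ) |> arrange(.data$subject_id, .data$visit_month)
  if (!is.null(truncation)) {
    w <- w |>
      group_by(.data$visit_month) |>
      mutate(ipcw = clamp(.data$ipcw,
                          quantile(.data$ipcw, truncation[1]),
                          quantile(.data$ipcw, truncation[2]))) |>
      ungroup()
  }
  w
}
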
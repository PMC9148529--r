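# Imposition of the three missingness types on a complete latent panel.
#
# Order of rule application per subject: drop-out is decided first, visit by
# visit; intermittent and component-missing are then drawn only on visits
# not already blanked by drop-out, which makes the three types mutually
# exclusive per visit. An intermittent gap is only drawn where a later
# non-blank visit will exist, so the ground-truth labels always satisfy the
# classifier's definitions exactly.

#' Missingness mechanism specification
#'
#' @param dropout Per-visit drop-out hazards for months 6/12/24 (probability
#'   of dropping at that visit given still in follow-up).
#' @param intermittent Per-visit probability of a fully missed visit with
#'   later re-entry, months 6/12 only (structurally impossible at the final
#'   visit).
#' @param component_missing Per-visit probability that a recorded visit has
#'   1-3 of the four DAS28 components missing.
#' @param mechanism `"MCAR"`, `"MAR"` or `"MNAR"`. Under MAR the drop-out
#'   hazard depends on observed covariates through `mar_coefficients`; MNAR
#'   additionally tilts the hazard by the to-be-blanked latent DAS28.
#' @param mar_coefficients Named log-odds coefficients on centred covariates;
#'   names may be baseline columns, `"das28_0"` (baseline DAS28) or
#'   `"das28_last"` (latent DAS28 at the previous scheduled visit).
#' @param mnar_delta Log-odds tilt per unit of the centred latent DAS28 at
#'   the visit being blanked (0 = MAR).
#' @return An `eca_missingness_spec` list.
#' @export
missingness_spec <- function(dropout = c(`6` = 0.024, `12` = 0.070, `24` = 0.285),
                             intermittent = c(`6` = 0.073, `12` = 0.113),
                             component_missing = c(`6` = 0.040, `12` = 0.046, `24` = 0.085),
                             mechanism = c("MCAR", "MAR", "MNAR"),
                             mar_coefficients = NULL,
                             mnar_delta = 0) {
  mechanism <- arg_match(mechanism)
  dropout <- normalize_probs(dropout, eca_visits(), "dropout")
  if (length(intermittent) == 3 &&
      !is.na(intermittent[3]) && intermittent[3] > 0) {
    abort("intermittent probability must be 0 at the final visit",
          class = "eca_error_spec")
  }
  intermittent <- normalize_probs(intermittent, c(6L, 12L), "intermittent")
  component_missing <- normalize_probs(component_missing, eca_visits(),
                                       "component_missing")
  if (!is.finite(mnar_delta)) abort("mnar_delta must be finite")
  structure(
    list(dropout = dropout, intermittent = intermittent,
         component_missing = component_missing, mechanism = mechanism,
         mar_coefficients = mar_coefficients, mnar_delta = mnar_delta),
    class = "eca_missingness_spec"
  )
}

normalize_probs <- function(p, visits, what) {
  p <- rep_len(unname(p), length(visits))
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    abort(sprintf("%s probabilities must be in [0, 1]", what),
          class = "eca_error_spec")
  }
  setNames(p, visits)
}

#' Trial-like and observational-like missingness presets
#'
#' The trial preset has monotone drop-out only, with per-visit hazards
#' 0.016/0.049/0.040 (cumulative 1.6%, 6.4%, 10.1%). The observational
#' preset adds intermittent missed visits at months 6/12 and partially
#' missing outcome components at all visits, with drop-out hazards chosen to
#' give cumulative drop-out of 2.4%, 9.2% and 35.1%.
#'
#' @return An [missingness_spec()] object.
#' @export
trial_missingness_spec <- function() {
  missingness_spec(dropout = c(`6` = 0.016, `12` = 0.049, `24` = 0.040),
                   intermittent = c(`6` = 0, `12` = 0),
                   component_missing = c(`6` = 0, `12` = 0, `24` = 0))
}

#' @rdname trial_missingness_spec
#' @export
observational_missingness_spec <- function() {
  missingness_spec()
}

#' Impose configurable missingness on a complete latent study
#'
#' @param study An `eca_study` from [simulate_study()] (or a single-cohort
#'   result from [generate_latent()]).
#' @param spec A single [missingness_spec()] applied to every cohort, or a
#'   named list of specs keyed by cohort.
#' @param seed Integer seed for the missingness draws.
#' @return An `eca_observed` list: `baseline`, `panel` (with `NA` holes),
#'   `labels` (the exact ground-truth record of which rule fired), `latent`
#'   (the pre-blanking panel), `truth` and `specs`.
#' @export
impose_missingness <- function(study, spec = observational_missingness_spec(),
                               seed = 1L) {
  stopifnot(inherits(study, "eca_study"))
  cohorts <- unique(study$baseline$cohort)
  specs <- if (inherits(spec, "eca_missingness_spec")) {
    setNames(rep(list(spec), length(cohorts)), cohorts)
  } else {
    missing_specs <- setdiff(cohorts, names(spec))
    if (length(missing_specs)) {
      abort(sprintf("no missingness spec for cohort(s): %s",
                    paste(missing_specs, collapse = ", ")))
    }
    spec
  }
  set.seed(substream_seed(seed, "missingness"))
  pieces <- lapply(cohorts, function(ch) {
    impose_one_cohort(
      baseline = filter(study$baseline, .data$cohort == ch),
      panel = filter(study$panel, .data$cohort == ch),
      spec = specs[[ch]]
    )
  })
  panel <- arrange(bind_rows(lapply(pieces, `[[`, "panel")),
                   .data$subject_id, .data$visit_month)
  labels <- arrange(bind_rows(lapply(pieces, `[[`, "labels")),
                    .data$subject_id, .data$visit_month)
  structure(
    list(baseline = study$baseline, panel = panel, labels = labels,
         latent = study$panel, truth = study$truth, specs = specs,
         seed = as.integer(seed)),
    class = "eca_observed"
  )
}

impose_one_cohort <- function(baseline, panel, spec) {
  visits <- eca_visits()
  subjects <- baseline$subject_id
  n <- length(subjects)
  # order rows to match the baseline subject order exactly
  panel <- panel[order(match(panel$subject_id, subjects), panel$visit_month), ]
  # latent DAS28 per visit (wide), for MAR("das28_last") and MNAR tilts
  sc <- add_das28(panel)
  das_w <- matrix(sc$das28[order(match(sc$subject_id, subjects), sc$visit_month)],
                  n, length(visits), byrow = TRUE)

  hazard_lp <- function(k, at_risk) {
    lp <- rep(qlogis_safe(spec$dropout[[k]]), sum(at_risk))
    if (spec$mechanism %in% c("MAR", "MNAR") && length(spec$mar_coefficients)) {
      for (nm in names(spec$mar_coefficients)) {
        x <- switch(nm,
          das28_0 = baseline$das28_0,
          das28_last = if (k == 1) baseline$das28_0 else das_w[, k - 1],
          baseline[[nm]] %||% abort(sprintf("unknown MAR covariate: %s", nm))
        )
        lp <- lp + spec$mar_coefficients[[nm]] * (x[at_risk] - mean(x))
      }
    }
    if (spec$mechanism == "MNAR" && spec$mnar_delta != 0) {
      lp <- lp + spec$mnar_delta * (das_w[at_risk, k] - mean(das_w[, k]))
    }
    lp
  }

  # 1. drop-out, visit by visit among those still in follow-up
  drop_at <- rep(Inf, n)
  for (k in seq_along(visits)) {
    at_risk <- is.infinite(drop_at)
    if (!any(at_risk) || spec$dropout[[k]] == 0) next
    if (spec$dropout[[k]] >= 1) {
      drop_at[at_risk] <- visits[k]
      next
    }
    p <- plogis(hazard_lp(k, at_risk))
    hit <- runif(sum(at_risk)) < p
    drop_at[at_risk][hit] <- visits[k]
  }

  # 2. intermittent at 6/12, only where a later non-blank visit will exist
  int12 <- drop_at > 24 & runif(n) < spec$intermittent[["12"]]
  elig6 <- drop_at > 24 | (drop_at == 24 & !int12)
  int6 <- elig6 & runif(n) < spec$intermittent[["6"]]
  intermittent <- cbind(`6` = int6, `12` = int12, `24` = rep(FALSE, n))

  # 3. partially missing components at retained visits
  lab <- matrix("observed", n, length(visits), dimnames = list(NULL, visits))
  blank <- matrix(FALSE, n, length(visits))
  comp_mask <- matrix(FALSE, n * length(visits), 4,
                      dimnames = list(NULL, eca_components()))
  for (k in seq_along(visits)) {
    dropped <- drop_at <= visits[k]
    lab[dropped, k] <- "dropout"
    lab[intermittent[, k], k] <- "intermittent"
    blank[, k] <- dropped | intermittent[, k]
    open <- which(!blank[, k])
    if (length(open) && spec$component_missing[[k]] > 0) {
      hit <- open[runif(length(open)) < spec$component_missing[[k]]]
      for (i in hit) {
        # 1-3 components so the visit stays distinguishable from a missed one
        js <- sample.int(4, sample.int(3, 1))
        comp_mask[(i - 1) * length(visits) + k, js] <- TRUE
        lab[i, k] <- "missing_at_visit"
      }
    }
  }

  out_panel <- panel
  blank_rows <- which(as.vector(t(blank)))
  for (j in seq_along(eca_components())) {
    nm <- eca_components()[j]
    idx <- union(blank_rows, which(comp_mask[, j]))
    if (length(idx)) out_panel[[nm]][idx] <- NA
  }
  labels <- tibble(
    subject_id = rep(subjects, each = length(visits)),
    cohort = baseline$cohort[1],
    visit_month = rep(visits, times = n),
    label = factor(as.vector(t(lab)), levels = eca_labels())
  )
  list(panel = out_panel, labels = labels)
}

qlogis_safe <- function(p) qlogis(clamp(p, 1e-12, 1 - 1e-12))

#' @export
print.eca_observed <- function(x, ...) {
  cat("Observed two-cohort panel with imposed missingness\n")
  print(summarize_patterns(x$labels)$summary)
  invisible(x)
}
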
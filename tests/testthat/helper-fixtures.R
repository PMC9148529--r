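# Small hand-built fixtures used across test files.

# A long aligned panel for given per-visit component rows.
# visits_list: named list subject_id -> list of per-visit component vectors
# (NULL = fully blank visit), in 6/12/24 order.
tiny_panel <- function(visits_list, cohort = "observational") {
  rows <- list()
  for (sid in names(visits_list)) {
    vv <- visits_list[[sid]]
    for (k in 1:3) {
      comp <- vv[[k]]
      if (is.null(comp)) comp <- rep(NA_real_, 4)
      rows[[length(rows) + 1]] <- tibble::tibble(
        subject_id = sid, cohort = cohort, visit_month = c(6L, 12L, 24L)[k],
        tjc28 = comp[1], sjc28 = comp[2], esr = comp[3], pga = comp[4]
      )
    }
  }
  dplyr::bind_rows(rows)
}

obs_visit <- function() c(2, 1, 20, 40)     # a fully observed visit
partial_visit <- function() c(2, 1, NA, 40) # ESR missing

# A small simulated study with both cohorts and preset missingness.
small_observed <- function(n_trial = 120, n_obs = 180, seed = 101,
                           spec_trial = trial_missingness_spec(),
                           spec_obs = observational_missingness_spec()) {
  s <- simulate_study(n_trial = n_trial, n_observational = n_obs, seed = seed)
  impose_missingness(
    s, spec = list(trial = spec_trial, observational = spec_obs), seed = seed
  )
}

fast_options <- function(...) {
  defaults <- list(m = 3, n_iterations = 3, min_at_risk = 5)
  args <- utils::modifyList(defaults, list(...))
  do.call(analysis_options, args)
}
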
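# Readers/writers, run configuration and the end-to-end driver.

panel_schema <- function() {
  c(subject_id = "character", cohort = "character", visit_month = "integer",
    tjc28 = "double", sjc28 = "double", esr = "double", pga = "double")
}

#' Read / write a long visit panel
#'
#' CSV with columns `subject_id`, `cohort`, `visit_month`, `tjc28`, `sjc28`,
#' `esr`, `pga`; empty fields encode missing values (never sentinel
#' numbers). Reading validates the schema (unknown or absent columns are
#' named in the error) and that visits are on the 6/12/24 schedule.
#'
#' @param path File path.
#' @param panel Panel table to write.
#' @return `read_panel()` returns a tibble; `write_panel()` its path,
#'   invisibly.
#' @export
read_panel <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE, na = c("", "NA"))
  sch <- panel_schema()
  extra <- setdiff(names(x), names(sch))
  if (length(extra)) {
    abort(sprintf("unknown column(s) in panel: %s", paste(extra, collapse = ", ")),
          class = "eca_error_schema")
  }
  assert_columns(x, names(sch), "panel")
  bad <- setdiff(unique(x$visit_month), eca_visits())
  if (length(bad)) {
    abort(sprintf("off-schedule visit_month in panel: %s",
                  paste(bad, collapse = ", ")),
          class = "eca_error_schema")
  }
  mutate(x, visit_month = as.integer(.data$visit_month))
}

#' @rdname read_panel
#' @export
write_panel <- function(panel, path) {
  assert_columns(panel, names(panel_schema()), "panel")
  readr::write_csv(panel[names(panel_schema())], path, na = "")
  invisible(path)
}

#' Read / write a baseline table
#' @param path File path.
#' @param baseline Baseline table.
#' @return A tibble, or the path invisibly.
#' @export
read_baseline <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE, na = c("", "NA"))
  assert_columns(x, c("subject_id", "cohort", eca_covariates()), "baseline")
  if (!"das28_0" %in% names(x)) {
    x <- mutate(x, das28_0 = das28(.data$tjc28_0, .data$sjc28_0,
                                   .data$esr_0, .data$pga_0))
  }
  x
}

#' @rdname read_baseline
#' @export
write_baseline <- function(baseline, path) {
  readr::write_csv(baseline, path, na = "")
  invisible(path)
}

#' Read / write a missingness label table
#' @param path File path.
#' @param labels Label table.
#' @return A tibble, or the path invisibly.
#' @export
read_labels <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  assert_columns(x, c("subject_id", "visit_month", "label"), "labels")
  mutate(x, visit_month = as.integer(.data$visit_month),
         label = factor(.data$label, levels = eca_labels()))
}

#' @rdname read_labels
#' @export
write_labels <- function(labels, path) {
  readr::write_csv(labels, path, na = "")
  invisible(path)
}

#' Run configuration
#'
#' A fully serializable description of one simulated study and its
#' analysis; [read_run_config()] / [write_run_config()] round-trip it
#' through YAML, and the same config always reproduces identical outputs.
#'
#' @param n_trial,n_observational Cohort sizes.
#' @param strategy_log_or,p_remission Generator truth, see
#'   [simulate_study()].
#' @param shift_observational Observational-cohort covariate shift.
#' @param trial_missingness,observational_missingness Per-cohort
#'   [missingness_spec()]s.
#' @param approaches Approaches to run.
#' @param options [analysis_options()].
#' @param seed Global seed, split deterministically into per-stage streams.
#' @return An `eca_run_config` list.
#' @export
run_config <- function(n_trial = 188, n_observational = 328,
                       strategy_log_or = c(`6` = 0.4, `12` = 0.7, `24` = 0.4),
                       p_remission = c(`6` = 0.35, `12` = 0.45, `24` = 0.55),
                       shift_observational = eca_default_shift(),
                       trial_missingness = trial_missingness_spec(),
                       observational_missingness = observational_missingness_spec(),
                       approaches = eca_approaches(),
                       options = analysis_options(),
                       seed = 1L) {
  structure(as.list(environment()), class = "eca_run_config")
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- run_config()
  for (nm in intersect(names(raw), names(cfg))) {
    delist <- function(x) {
      lapply(x, function(v) if (is.list(v) && !any(vapply(v, is.list, TRUE))) unlist(v) else v)
    }
    cfg[[nm]] <- switch(nm,
      trial_missingness = ,
      observational_missingness = do.call(missingness_spec, delist(raw[[nm]])),
      options = do.call(analysis_options, delist(raw[[nm]])),
      strategy_log_or = ,
      p_remission = unlist(raw[[nm]]),
      shift_observational = unlist(raw[[nm]]),
      raw[[nm]]
    )
  }
  cfg
}

#' @rdname run_config
#' @param config An `eca_run_config`.
#' @export
write_run_config <- function(config, path) {
  ser <- lapply(config, function(x) {
    if (inherits(x, c("eca_missingness_spec", "eca_options"))) {
      lapply(unclass(x), function(v) if (is.numeric(v) && !is.null(names(v))) as.list(v) else v)
    } else if (is.numeric(x) && !is.null(names(x))) as.list(x) else x
  })
  yaml::write_yaml(ser, path)
  invisible(path)
}

#' Run the whole pipeline on one configuration
#'
#' Simulate the two cohorts, impose missingness, verify the ground-truth
#' labels against the classifier, balance the cohorts by IPTW, run the
#' requested approaches, and assemble the per-visit effect report, per-arm
#' remission proportions, missingness pattern summaries, balance table and
#' a reproducibility manifest.
#'
#' @param config An [run_config()].
#' @return An `eca_run` list: `comparison`, `patterns`, `balance`,
#'   `observed`, `manifest`.
#' @export
run_end_to_end <- function(config = run_config()) {
  stopifnot(inherits(config, "eca_run_config"))
  study <- simulate_study(
    n_trial = config$n_trial, n_observational = config$n_observational,
    strategy_log_or = config$strategy_log_or, p_remission = config$p_remission,
    shift_observational = config$shift_observational, seed = config$seed
  )
  observed <- impose_missingness(
    study,
    spec = list(trial = config$trial_missingness,
                observational = config$observational_missingness),
    seed = config$seed
  )
  opts <- config$options
  opts$seed <- substream_seed(config$seed, "imputation")
  comparison <- compare_approaches(observed, approaches = config$approaches,
                                   options = opts)
  balance <- balance_table(observed$baseline, comparison$iptw,
                           covariates = opts$covariates)
  manifest <- list(
    package_version = as.character(packageVersion("ecamiss")),
    seed = config$seed,
    n_trial = config$n_trial, n_observational = config$n_observational,
    strategy_log_or = config$strategy_log_or,
    m = opts$m, timestamp = format(Sys.time(), tz = "UTC")
  )
  structure(
    list(comparison = comparison,
         patterns = summarize_patterns(observed$labels),
         balance = balance, observed = observed, manifest = manifest,
         config = config),
    class = "eca_run"
  )
}

#' Persist a run bundle as plain-text files
#'
#' Writes the effects report, proportions, label table, panels, balance
#' diagnostics and manifest under `dir`.
#'
#' @param run An [run_end_to_end()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run_bundle <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(run$comparison$effects, file.path(dir, "effects.csv"))
  readr::write_csv(run$comparison$proportions, file.path(dir, "proportions.csv"))
  readr::write_csv(run$balance, file.path(dir, "balance.csv"))
  write_panel(run$observed$panel, file.path(dir, "panel.csv"))
  write_baseline(run$observed$baseline, file.path(dir, "baseline.csv"))
  write_labels(run$observed$labels, file.path(dir, "labels.csv"))
  readr::write_csv(run$patterns$by_visit, file.path(dir, "patterns.csv"))
  yaml::write_yaml(run$manifest, file.path(dir, "manifest.yml"))
  invisible(dir)
}

#' @export
print.eca_run <- function(x, ...) {
  print(x$comparison)
  invisible(x)
}
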
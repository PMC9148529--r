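#' Classify each subject-visit into the three missingness types
#'
#' On a schedule-aligned panel, a visit is `observed` when the DAS28 is
#' computable (all four components present); `missing_at_visit` when the
#' visit was recorded but at least one component is absent; a fully blank
#' visit is `intermittent` when any later visit is non-blank and `dropout`
#' otherwise. Drop-out propagates: every visit at or after the first
#' drop-out visit is labelled `dropout`.
#'
#' @param panel Schedule-aligned long panel (`subject_id`, `visit_month`,
#'   components; optionally `cohort`). Visits absent from the table count as
#'   fully blank.
#' @return Tibble `subject_id` (+ `cohort`), `visit_month`, `label`.
#' @export
classify_missingness <- function(panel) {
  assert_columns(panel, c("subject_id", "visit_month", eca_components()), "panel")
  visits <- eca_visits()
  bad <- setdiff(unique(panel$visit_month), visits)
  if (length(bad)) {
    abort(sprintf("panel contains off-schedule visit_month: %s",
                  paste(bad, collapse = ", ")),
          class = "eca_error_schema")
  }
  subjects <- unique(panel$subject_id)
  n <- length(subjects)
  # wide logical matrices: any component missing / all components missing
  idx <- cbind(
    match(panel$subject_id, subjects),
    match(panel$visit_month, visits)
  )
  n_miss <- matrix(4L, n, length(visits)) # absent rows = fully blank
  comp <- as.matrix(panel[, eca_components()])
  n_miss[idx] <- rowSums(is.na(comp))
  blank <- n_miss == 4L
  partial <- n_miss > 0L & n_miss < 4L

  # dropout = maximal all-blank tail; scan visits right to left
  tail_blank <- blank
  for (j in rev(seq_along(visits))[-1]) {
    tail_blank[, j] <- blank[, j] & tail_blank[, j + 1L]
  }
  lab <- matrix("observed", n, length(visits))
  lab[partial] <- "missing_at_visit"
  lab[blank] <- "intermittent"
  lab[tail_blank] <- "dropout"

  out <- tibble(
    subject_id = rep(subjects, times = length(visits)),
    visit_month = rep(visits, each = n),
    label = factor(as.vector(lab), levels = eca_labels())
  )
  if ("cohort" %in% names(panel)) {
    out <- left_join(out, distinct(panel, .data$subject_id, .data$cohort),
                     by = "subject_id") |>
      select("subject_id", "cohort", "visit_month", "label")
  }
  arrange(out, .data$subject_id, .data$visit_month)
}

#' Summarise longitudinal missingness patterns
#'
#' Per-visit proportions of each missingness label, the fraction of subjects
#' with complete follow-up (all visits observed), and whether the pattern is
#' monotone, i.e. no subject has an unavailable outcome followed by an
#' available one.
#'
#' @param labels Label table from [classify_missingness()] (or generator
#'   ground truth). A `cohort` column, if present, stratifies the summary.
#' @return An `eca_patterns` object; `tidy()` returns the per-visit table.
#' @export
summarize_patterns <- function(labels) {
  assert_columns(labels, c("subject_id", "visit_month", "label"), "labels")
  grp <- intersect("cohort", names(labels))
  by_visit <- labels |>
    group_by(dplyr::across(dplyr::all_of(c(grp, "visit_month")))) |>
    count(.data$label, .drop = FALSE) |>
    mutate(proportion = .data$n / sum(.data$n)) |>
    ungroup()

  per_subject <- labels |>
    group_by(dplyr::across(dplyr::all_of(c(grp, "subject_id")))) |>
    arrange(.data$visit_month, .by_group = TRUE) |>
    summarise(
      complete = all(.data$label == "observed"),
      # available = DAS28 computable at that visit
      nonmono = {
        avail <- .data$label == "observed"
        any(!avail & rev(cumsum(rev(avail)) > 0))
      },
      .groups = "drop"
    )
  summary_tbl <- per_subject |>
    group_by(dplyr::across(dplyr::all_of(grp))) |>
    summarise(
      n_subjects = dplyr::n(),
      complete_fraction = mean(.data$complete),
      monotone = !any(.data$nonmono),
      .groups = "drop"
    )
  structure(
    list(by_visit = by_visit, summary = summary_tbl),
    class = "eca_patterns"
  )
}

#' @export
print.eca_patterns <- function(x, ...) {
  cat("Missing-data patterns\n")
  print(x$summary)
  print(x$by_visit, n = Inf)
  invisible(x)
}
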
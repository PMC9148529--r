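#' Map raw visit times onto the 6/12/24-month schedule
#'
#' Observational follow-up visits rarely land exactly on the scheduled month.
#' Each target month is assigned the nearest raw visit inside its window;
#' distance ties resolve to the *later* raw visit (observational visits tend
#' to occur after, not before, schedule). Each raw visit is used at most
#' once; an unmatched target becomes a fully blank visit. Windows must not
#' overlap, so no raw visit is ever eligible for two targets.
#'
#' @param raw_visits Long table with `subject_id`, `visit_month` (raw months,
#'   numeric) and the DAS28 component columns.
#' @param targets Scheduled months, default `c(6, 12, 24)`.
#' @param windows Either a single half-width, a numeric vector of half-widths
#'   (one per target), or a data frame with columns `target`, `lower`,
#'   `upper` giving absolute window bounds in months.
#' @return A schedule-aligned tibble with one row per subject and target
#'   month; `source_month` records which raw visit supplied the data (`NA`
#'   when the target is blank).
#' @export
map_visits <- function(raw_visits, targets = eca_visits(), windows = 2) {
  assert_columns(raw_visits, c("subject_id", "visit_month", eca_components()),
                 "raw_visits")
  win <- normalize_windows(targets, windows)
  if (any(win$lower[-1] <= win$upper[-nrow(win)])) {
    abort("visit windows overlap", class = "eca_error_windows")
  }
  extra <- intersect("cohort", names(raw_visits))

  assigned <- raw_visits |>
    dplyr::cross_join(win) |>
    filter(.data$visit_month >= .data$lower, .data$visit_month <= .data$upper) |>
    mutate(dist = abs(.data$visit_month - .data$target)) |>
    group_by(.data$subject_id, .data$target) |>
    # nearest raw visit; ties go to the later one
    arrange(.data$dist, dplyr::desc(.data$visit_month), .by_group = TRUE) |>
    slice(1L) |>
    ungroup()

  grid <- tidyr::expand_grid(
    subject_id = unique(raw_visits$subject_id),
    target = sort(targets)
  )
  out <- grid |>
    left_join(
      select(assigned, "subject_id", "target",
             source_month = "visit_month", dplyr::all_of(c(extra, eca_components()))),
      by = c("subject_id", "target")
    ) |>
    rename(visit_month = "target")
  if (length(extra)) {
    subj <- distinct(raw_visits, .data$subject_id, .data$cohort)
    out <- out |>
      select(-dplyr::all_of(extra)) |>
      left_join(subj, by = "subject_id") |>
      select("subject_id", "cohort", dplyr::everything())
  }
  as_tibble(out)
}

normalize_windows <- function(targets, windows) {
  if (is.data.frame(windows)) {
    assert_columns(windows, c("target", "lower", "upper"), "windows")
    win <- as_tibble(windows)
  } else {
    if (length(windows) == 1) windows <- rep(windows, length(targets))
    if (length(windows) != length(targets)) {
      abort("windows must have length 1 or length(targets)")
    }
    win <- tibble(target = targets, lower = targets - windows,
                  upper = targets + windows)
  }
  arrange(win, .data$target)
}
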
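# DAS28-ESR composite and the remission endpoint.
#
# The standard four-component formula is pinned here in one constant block so
# that a CRP-based variant could be swapped in without touching callers.
.das28_coefs <- c(tjc28 = 0.56, sjc28 = 0.28, esr = 0.70, pga = 0.014)
.das28_remission_cutoff <- 2.6

#' Disease Activity Score in 28 joints (ESR-based)
#'
#' Computes `0.56*sqrt(TJC28) + 0.28*sqrt(SJC28) + 0.70*ln(ESR) + 0.014*PGA`.
#' Any missing component propagates to a missing score. An ESR of zero is
#' floored to 1 mm/h before the logarithm so the score stays finite.
#'
#' @param tjc28 Tender joint count in 28 joints, integer in `[0, 28]`.
#' @param sjc28 Swollen joint count in 28 joints, integer in `[0, 28]`.
#' @param esr Erythrocyte sedimentation rate, mm/h, non-negative.
#' @param pga Patient's global assessment of disease, mm VAS in `[0, 100]`.
#' @return Numeric vector of scores (range roughly 0 to 9.4); `NA` where any
#'   component is missing.
#' @examples
#' das28(4, 2, 20, 50)
#' das28(0, 0, 1, 0)
#' @export
das28 <- function(tjc28, sjc28, esr, pga) {
  check_component(tjc28, 0, 28, "tjc28")
  check_component(sjc28, 0, 28, "sjc28")
  check_component(esr, 0, Inf, "esr")
  check_component(pga, 0, 100, "pga")
  esr <- pmax(esr, 1)
  .das28_coefs[["tjc28"]] * sqrt(tjc28) +
    .das28_coefs[["sjc28"]] * sqrt(sjc28) +
    .das28_coefs[["esr"]] * log(esr) +
    .das28_coefs[["pga"]] * pga
}

check_component <- function(x, lo, hi, name) {
  bad <- !is.na(x) & (x < lo | x > hi)
  if (any(bad)) {
    abort(
      sprintf("%s out of range [%s, %s]: %s", name, lo, hi,
              paste(utils::head(x[bad], 3), collapse = ", ")),
      class = "eca_error_range"
    )
  }
  invisible(x)
}

#' Remission according to DAS28
#'
#' Remission is a score strictly below 2.6; a missing score yields a missing
#' indicator, never `FALSE`.
#'
#' @param score DAS28 score(s).
#' @return Logical vector.
#' @examples
#' das28_remission(c(2.59, 2.60, NA))
#' @export
das28_remission <- function(score) {
  score < .das28_remission_cutoff
}

#' Add DAS28 score and remission indicator to a visit panel
#'
#' @param panel Long panel with columns `tjc28`, `sjc28`, `esr`, `pga`.
#' @return The panel with `das28` and `remission` columns appended.
#' @export
add_das28 <- function(panel) {
  assert_columns(panel, eca_components(), "panel")
  dplyr::mutate(
    panel,
    das28 = das28(.data$tjc28, .data$sjc28, .data$esr, .data$pga),
    remission = das28_remission(.data$das28)
  )
}
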
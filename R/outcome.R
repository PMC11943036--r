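#' Derive the successful-extubation outcome day
#'
#' Successful extubation is an extubation not followed by reintubation
#' within seven days. `derive_outcomes()` adds an `outcome_day` column to a
#' registry: the day of the first extubation episode whose reintubation flag
#' is clear, provided that day falls within the horizon and precedes both
#' the death day and the loss-to-follow-up day; `NA` otherwise. The result
#' only depends on episodes up to the first qualifying one.
#'
#' An episode whose seven-day confirmation window is cut short by the end
#' of the observed data counts as a success when no reintubation was
#' recorded in the observed portion — the reintubation flag as recorded is
#' taken at face value. This optimistic truncation convention mirrors usual
#' ventilator-free-days scoring and is applied uniformly.
#'
#' @param subjects Registry tibble ([registry-schema]).
#' @param horizon Last follow-up day (default 45).
#' @return `subjects` with an integer `outcome_day` column appended.
#' @export
#' @examples
#' reg <- simulate_registry(sim_params(n_subjects = 20, seed = 5))
#' derive_outcomes(reg)[, c("subject_id", "extubation_episodes", "outcome_day")]
derive_outcomes <- function(subjects, horizon = 45L) {
  stopifnot(is_count(horizon))
  ep <- episodes_table(subjects)
  if (nrow(ep) == 0L) {
    subjects$outcome_day <- NA_integer_
    return(subjects)
  }
  qualifying <- ep |>
    dplyr::left_join(dplyr::select(subjects, "subject_id", "death_day",
                                   "ltfu_day"),
                     by = "subject_id") |>
    dplyr::filter(!.data$reintubated_within_7d,
                  .data$extubation_day <= horizon,
                  is.na(.data$death_day) | .data$extubation_day < .data$death_day,
                  is.na(.data$ltfu_day) | .data$extubation_day < .data$ltfu_day)
  if (nrow(qualifying) == 0L) {
    subjects$outcome_day <- NA_integer_
    return(subjects)
  }
  first_ok <- qualifying |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(outcome_day = min(.data$extubation_day), .groups = "drop")
  subjects$outcome_day <- NULL
  subjects |>
    dplyr::left_join(first_ok, by = "subject_id") |>
    dplyr::mutate(outcome_day = as.integer(.data$outcome_day))
}

#' @rdname derive_outcomes
#' @param episodes Tibble `(extubation_day, reintubated_within_7d)` for one
#'   subject.
#' @param death_day,ltfu_day Scalar event days or `NA`.
#' @return `derive_outcome_day()` returns a single integer day or `NA`.
#' @export
derive_outcome_day <- function(episodes, death_day = NA, ltfu_day = NA,
                               horizon = 45L) {
  if (is.null(episodes) || nrow(episodes) == 0L) return(NA_integer_)
  ok <- !episodes$reintubated_within_7d &
    episodes$extubation_day <= horizon &
    (is.na(death_day) | episodes$extubation_day < death_day) &
    (is.na(ltfu_day) | episodes$extubation_day < ltfu_day)
  if (!any(ok)) return(NA_integer_)
  as.integer(min(episodes$extubation_day[ok]))
}
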
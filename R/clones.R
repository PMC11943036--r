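#' Expand eligible subjects into per-strategy clones
#'
#' Each eligible subject contributes one clone to every strategy it is
#' compatible with at baseline. On the referral-day axis every subject is
#' compatible (nobody is treated before referral); on the postnatal-age axis
#' a subject whose referral age already exceeds the window's end, or who
#' violates the strategy's age-at-referral cap, cannot follow the strategy
#' and is excluded from that arm with a logged reason.
#'
#' @param eligible Eligible registry tibble, with `outcome_day` present
#'   (run [derive_outcomes()] first; it is added here if missing).
#' @param strategies Strategy tibble ([strategy()], [default_strategies()]).
#' @param horizon Follow-up horizon in days.
#' @return A tibble with one row per clone: `clone_id`, `subject_id`,
#'   `strategy`, the referral-clock window `ref_start`/`ref_end`, the event
#'   days, and `deviation_day` (see [deviation_day()]). Excluded
#'   subject-strategy pairs are attached as attribute `"excluded"`.
#' @export
#' @examples
#' reg <- derive_outcomes(simulate_registry(sim_params(n_subjects = 30, seed = 2)))
#' cl <- make_clones(apply_eligibility(reg)$eligible, default_strategies())
#' dplyr::count(cl, strategy, adherent = is.na(deviation_day))
make_clones <- function(eligible, strategies, horizon = 45L) {
  check_strategies(strategies)
  if (!"outcome_day" %in% names(eligible)) {
    eligible <- derive_outcomes(eligible, horizon = horizon)
  }
  win <- map_windows(eligible, strategies)
  excluded <- win |>
    dplyr::filter(!.data$compatible) |>
    dplyr::mutate(reason = "strategy window incompatible with age at referral") |>
    dplyr::select("subject_id", "strategy", "reason")
  clones <- win |>
    dplyr::filter(.data$compatible) |>
    dplyr::left_join(dplyr::select(eligible, "subject_id", "intervention_day",
                                   "outcome_day", "death_day", "ltfu_day"),
                     by = "subject_id") |>
    dplyr::mutate(clone_id = paste(.data$subject_id, .data$strategy, sep = "."),
                  deviation_day = deviation_day(.data$intervention_day,
                                                .data$outcome_day,
                                                .data$death_day,
                                                .data$ltfu_day,
                                                .data$ref_start,
                                                .data$ref_end)) |>
    dplyr::select("clone_id", "subject_id", "strategy", "ref_start", "ref_end",
                  "intervention_day", "outcome_day", "death_day", "ltfu_day",
                  "deviation_day")
  attr(clones, "excluded") <- excluded
  clones
}

#' Day of deviation from an assigned strategy
#'
#' A clone deviates from its strategy when (a) the intervention occurs
#' strictly before the window start — censored on the intervention day — or
#' (b) it is still untreated at the end of the window's last day — censored
#' on that day. No deviation occurs when the intervention falls inside the
#' window, or when the outcome, death, or loss to follow-up precedes the
#' would-be deviation. Same-day ties follow the fixed precedence *event
#' before deviation before administrative censoring*; death (evaluated
#' before any same-day initiation opportunity) also pre-empts a same-day
#' deviation, so a clone dying untreated inside the grace period is retained
#' as a non-deviating non-event through the horizon.
#'
#' @param intervention_day,outcome_day,death_day,ltfu_day Integer event-day
#'   vectors (`NA` = never).
#' @param ref_start,ref_end Strategy window on the referral clock.
#' @return Integer vector of deviation days (`NA` = adherent).
#' @export
deviation_day <- function(intervention_day, outcome_day, death_day, ltfu_day,
                          ref_start, ref_end) {
  treated_in <- !is.na(intervention_day) &
    intervention_day >= ref_start & intervention_day <= ref_end
  early_dev <- !is.na(intervention_day) & intervention_day < ref_start
  cand <- dplyr::case_when(
    treated_in ~ NA_integer_,
    early_dev ~ as.integer(intervention_day),
    .default = as.integer(ref_end)
  )
  pre_empted <-
    (!is.na(outcome_day) & outcome_day <= cand) |   # event wins same-day ties
    (!is.na(death_day) & death_day <= cand) |       # dead before initiation step
    (!is.na(ltfu_day) & ltfu_day < cand)            # deviation beats same-day LTFU
  dplyr::if_else(!is.na(cand) & pre_empted, NA_integer_, cand)
}

#' Expand clones into the person-day (clone-day) table
#'
#' One row per clone per follow-up day from day 0 up to the clone's terminal
#' day: the event day, the artificial-censoring (deviation) day, or the
#' administrative end (loss to follow-up or the horizon), whichever comes
#' first — with the precedence *event, then deviation, then administrative
#' censoring* on ties. Under the total-effect estimand (`competing =
#' "total"`), death does not terminate rows: dead clones persist with
#' `event = 0` through the horizon, so deaths count as never extubated.
#' Under `competing = "censor_death"` (controlled direct effect), rows are
#' truncated at death: the last row is the day before death, since death is
#' evaluated before the extubation attempt within a day, so the clone is not
#' at risk on the death day itself.
#'
#' @param clones Clone tibble from [make_clones()].
#' @param horizon Last follow-up day.
#' @param competing `"total"` (deaths carried forward as non-events) or
#'   `"censor_death"` (rows truncated at death).
#' @return Clone-day tibble with columns `clone_id`, `subject_id`,
#'   `strategy`, `day`, `treated_by_t`, `at_risk`, `event`,
#'   `artificial_censor`, `admin_censor`, `dead_by_t`.
#' @export
expand_person_days <- function(clones, horizon = 45L,
                               competing = c("total", "censor_death")) {
  competing <- match.arg(competing)
  horizon <- as.integer(horizon)

  d_event <- dplyr::if_else(!is.na(clones$outcome_day) &
                              clones$outcome_day <= horizon,
                            clones$outcome_day, NA_integer_)
  d_dev <- clones$deviation_day
  d_admin <- pmin(dplyr::coalesce(clones$ltfu_day, horizon), horizon)
  if (competing == "censor_death") {
    d_admin <- pmin(d_admin,
                    dplyr::coalesce(clones$death_day - 1L, horizon))
  }
  end <- pmin(dplyr::coalesce(d_event, horizon),
              dplyr::coalesce(d_dev, horizon),
              d_admin)
  terminal <- dplyr::case_when(
    !is.na(d_event) & d_event == end ~ "event",
    !is.na(d_dev) & d_dev == end ~ "deviation",
    .default = "admin"
  )
  keep <- end >= 0L  # censor_death with death on day 0 contributes no rows
  clones <- clones[keep, , drop = FALSE]
  end <- end[keep]
  terminal <- terminal[keep]
  if (nrow(clones) == 0L) {
    return(tibble::tibble(clone_id = character(0), subject_id = character(0),
                          strategy = character(0), day = integer(0),
                          treated_by_t = logical(0), at_risk = logical(0),
                          event = integer(0), artificial_censor = integer(0),
                          admin_censor = integer(0), dead_by_t = logical(0)))
  }

  n_rows <- end + 1L
  i <- rep.int(seq_len(nrow(clones)), n_rows)
  day <- sequence(n_rows) - 1L
  last <- day == rep.int(end, n_rows)
  int_day <- clones$intervention_day[i]
  death <- clones$death_day[i]
  tibble::tibble(
    clone_id = clones$clone_id[i],
    subject_id = clones$subject_id[i],
    strategy = clones$strategy[i],
    day = day,
    treated_by_t = !is.na(int_day) & int_day <= day,
    dead_by_t = !is.na(death) & death <= day,
    event = as.integer(last & rep.int(terminal == "event", n_rows)),
    artificial_censor = as.integer(last & rep.int(terminal == "deviation", n_rows)),
    admin_censor = as.integer(last & rep.int(terminal == "admin", n_rows))
  ) |>
    dplyr::mutate(at_risk = !.data$dead_by_t,
                  .after = "treated_by_t")
}

#' Adherence flow summary
#'
#' Counts subjects by their pattern of strategy adherence (no artificial
#' censoring over follow-up): adherent to each single strategy, to both, or
#' to neither — the flowchart view of the cloned population.
#'
#' @param clones Clone tibble from [make_clones()] (two-strategy sets give
#'   the classical early/late/both/neither split).
#' @return A tibble `(pattern, n)`.
#' @export
adherence_flow <- function(clones) {
  pat <- clones |>
    dplyr::mutate(adherent = is.na(.data$deviation_day)) |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(
      pattern = if (all(.data$adherent)) "both" else
        if (!any(.data$adherent)) "neither" else
          paste(sort(.data$strategy[.data$adherent]), collapse = "+"),
      .groups = "drop")
  dplyr::count(pat, .data$pattern, name = "n")
}
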
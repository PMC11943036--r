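#' Mean ventilator days from a cumulative-incidence curve
#'
#' The expected number of days on invasive ventilation over follow-up,
#' `sum_(t=1..horizon) (1 - CI(t))` — the restricted mean time to
#' successful extubation. Under the total-effect convention deaths never
#' reach the outcome, so they contribute as intubated through the horizon.
#'
#' @param curves Risk-curve tibble `(strategy, day, cum_inc)` from
#'   [risk_curves()].
#' @param horizon Last follow-up day (curve must cover days `1:horizon`).
#' @return Tibble `(strategy, mean_vent_days)`.
#' @export
mean_ventilator_days <- function(curves, horizon = 45L) {
  stopifnot(all(c("strategy", "day", "cum_inc") %in% names(curves)))
  curves |>
    dplyr::filter(.data$day >= 1, .data$day <= horizon) |>
    dplyr::group_by(.data$strategy) |>
    dplyr::summarise(mean_vent_days = sum(1 - .data$cum_inc),
                     .groups = "drop")
}

#' Per-day risk differences and the selected-day effect table
#'
#' Risk differences between each strategy and the reference strategy at
#' every follow-up day, plus the conventional day 7/14/30/45 summary and
#' mean ventilator days. Percentages are reported on the 0-1 scale here;
#' multiply by 100 for percentage points.
#'
#' @param curves Risk-curve tibble from [risk_curves()].
#' @param ref Reference strategy name (default: the last strategy, so the
#'   default early/late pair reports early minus late).
#' @param selected_days Days for the summary table.
#' @param horizon Last follow-up day.
#' @return A list of class `ccw_effect_report`: `rd` (tibble `strategy,
#'   day, rd`), `selected` (wide summary at the selected days),
#'   `mean_vent_days` (per strategy plus differences vs the reference).
#' @export
effect_report <- function(curves, ref = NULL,
                          selected_days = c(7L, 14L, 30L, 45L),
                          horizon = 45L) {
  strategies <- unique(curves$strategy)
  if (is.null(ref)) ref <- strategies[length(strategies)]
  if (!ref %in% strategies) {
    stop("reference strategy '", ref, "' not in curves", call. = FALSE)
  }
  ref_curve <- curves |>
    dplyr::filter(.data$strategy == ref) |>
    dplyr::select("day", ref_ci = "cum_inc")
  rd <- curves |>
    dplyr::filter(.data$strategy != ref) |>
    dplyr::left_join(ref_curve, by = "day") |>
    dplyr::mutate(rd = .data$cum_inc - .data$ref_ci) |>
    dplyr::select("strategy", "day", "rd")

  sel_ci <- curves |>
    dplyr::filter(.data$day %in% selected_days) |>
    dplyr::select("strategy", "day", value = "cum_inc") |>
    dplyr::mutate(quantity = paste0("cum_inc_", .data$strategy))
  sel_rd <- rd |>
    dplyr::filter(.data$day %in% selected_days) |>
    dplyr::select("strategy", "day", value = "rd") |>
    dplyr::mutate(quantity = paste0("rd_", .data$strategy, "_vs_", ref))
  selected <- dplyr::bind_rows(sel_ci, sel_rd) |>
    dplyr::select("quantity", "day", "value") |>
    tidyr::pivot_wider(names_from = "day", names_prefix = "day_",
                       values_from = "value")

  mvd <- mean_ventilator_days(curves, horizon = horizon)
  mvd_ref <- mvd$mean_vent_days[mvd$strategy == ref]
  mvd$diff_vs_ref <- mvd$mean_vent_days - mvd_ref

  structure(list(rd = rd, selected = selected, mean_vent_days = mvd,
                 ref = ref, selected_days = selected_days),
            class = "ccw_effect_report")
}

#' @export
print.ccw_effect_report <- function(x, ...) {
  cat("<ccw_effect_report> reference strategy:", x$ref, "\n")
  print(x$selected)
  cat("mean ventilator days:\n")
  print(x$mean_vent_days)
  invisible(x)
}

#' @export
tidy.ccw_effect_report <- function(x, ...) x$rd

#' Weighted baseline characteristics at the end of the grace period
#'
#' Summarises each strategy's clone population that reached the end of its
#' grace window without artificial censoring, unweighted and weighted by
#' the inverse-probability weights (frozen at the end of the window). In
#' the weighted pseudo-population the censoring-induced covariate selection
#' should be undone, so the strategies' columns should resemble the full
#' eligible cohort.
#'
#' @param clones Clone table from [make_clones()].
#' @param weights Weight table from [compute_weights()] (or `NULL` for
#'   weights 1).
#' @param subjects Registry tibble supplying the covariates.
#' @param continuous,binary Covariate columns to summarise as weighted
#'   median \[IQR\] and as weighted percentages. A character `binary`
#'   column is summarised as percentage of its first sorted level.
#' @param weight_col `"sw"` or `"w"`.
#' @return Tibble `(variable, strategy, unweighted, weighted)` of formatted
#'   summaries; pseudo-population sizes appear as the first row. Class
#'   `ccw_baseline_table`.
#' @export
baseline_table <- function(clones, weights = NULL, subjects,
                           continuous = c("birth_weight_g",
                                          "gestational_age_weeks",
                                          "age_at_referral_days",
                                          "referral_year"),
                           binary = c("sex", "prior_pharmacotherapy"),
                           weight_col = c("sw", "w")) {
  weight_col <- match.arg(weight_col)
  adherent <- dplyr::filter(clones, is.na(.data$deviation_day))
  if (is.null(weights)) {
    adherent$.w <- 1
  } else {
    w_end <- weights |>
      dplyr::group_by(.data$clone_id) |>
      dplyr::summarise(.w = .data[[weight_col]][which.max(.data$day)],
                       .groups = "drop")
    adherent <- dplyr::left_join(adherent, w_end, by = "clone_id")
    adherent$.w <- dplyr::coalesce(adherent$.w, 1)
  }
  adherent <- dplyr::left_join(
    adherent,
    dplyr::select(subjects, "subject_id",
                  dplyr::all_of(unique(c(continuous, binary)))),
    by = "subject_id"
  )

  summarise_arm <- function(df) {
    rows <- list(tibble::tibble(
      variable = "n",
      unweighted = as.character(nrow(df)),
      weighted = sprintf("%.1f", sum(df$.w))
    ))
    for (v in continuous) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        variable = paste0(v, ", median [IQR]"),
        unweighted = fmt_med_iqr(df[[v]], rep(1, nrow(df))),
        weighted = fmt_med_iqr(df[[v]], df$.w)
      )
    }
    for (v in binary) {
      x <- df[[v]]
      if (is.character(x) || is.factor(x)) {
        lev <- sort(unique(as.character(x)))[1]
        x <- as.character(x) == lev
        label <- paste0(v, " = ", lev, " (%)")
      } else {
        x <- as.logical(x)
        label <- paste0(v, " (%)")
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        variable = label,
        unweighted = sprintf("%.1f", 100 * mean(x)),
        weighted = sprintf("%.1f", 100 * sum(df$.w * x) / sum(df$.w))
      )
    }
    dplyr::bind_rows(rows)
  }

  out <- adherent |>
    dplyr::group_by(.data$strategy) |>
    dplyr::group_modify(~ summarise_arm(.x)) |>
    dplyr::ungroup() |>
    dplyr::select("variable", "strategy", "unweighted", "weighted")
  class(out) <- c("ccw_baseline_table", class(out))
  out
}
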
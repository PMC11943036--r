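#' Registry CSV schema
#'
#' The registry holds one row per referred infant on the referral clock
#' (day 0 = referral; all event days are non-negative integers, closed
#' intervals). Mandatory columns:
#'
#' * `subject_id` — unique identifier.
#' * `gestational_age_weeks`, `birth_weight_g`, `age_at_referral_days`,
#'   `sex` (`"female"`/`"male"`), `referral_year`,
#'   `prior_pharmacotherapy`, `pharmacotherapy_contraindicated` — baseline
#'   covariates and pharmacotherapy history.
#' * `ventilated_at_referral`, `complex_chd`, `bidirectional_or_r2l_flow`,
#'   `major_anomaly`, `tracheostomy` — eligibility flags.
#' * `intervention_day` — day of definitive closure, empty if none.
#' * `extubation_episodes` — semicolon-separated `day:reintubated` pairs,
#'   e.g. `"10:1;20:0"` (`1` = reintubated within seven days), empty if
#'   none; days strictly increasing.
#' * `death_day`, `ltfu_day` — day of death / loss to follow-up, empty if
#'   none.
#'
#' `referral_site` and any other columns are optional and preserved
#' untouched.
#'
#' @name registry-schema
NULL

registry_mandatory_cols <- c(
  "subject_id", "gestational_age_weeks", "birth_weight_g",
  "age_at_referral_days", "sex", "referral_year", "prior_pharmacotherapy",
  "pharmacotherapy_contraindicated", "ventilated_at_referral", "complex_chd",
  "bidirectional_or_r2l_flow", "major_anomaly", "tracheostomy",
  "intervention_day", "extubation_episodes", "death_day", "ltfu_day"
)

registry_event_cols <- c("intervention_day", "death_day", "ltfu_day")

#' Read or write a registry CSV
#'
#' `read_registry()` parses and validates a registry file in the schema of
#' [registry-schema]; `write_registry()` writes one (missing event days as
#' empty cells, a `#`-comment header line recording the simulation seed when
#' the table carries one). The pair round-trips: writing and re-reading
#' returns the schema columns unchanged.
#'
#' @param path File path.
#' @param subjects Registry tibble.
#' @return `read_registry()` returns a validated tibble; `write_registry()`
#'   returns `subjects` invisibly.
#' @export
read_registry <- function(path) {
  raw <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE,
                         col_types = readr::cols(.default = readr::col_guess()))
  missing <- setdiff(registry_mandatory_cols, names(raw))
  if (length(missing) > 0) {
    stop("registry is missing mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (col in registry_event_cols) {
    v <- raw[[col]]
    if (is.logical(v)) v <- as.integer(v)  # all-NA or empty column
    bad <- if (is.numeric(v)) {
      which(!is.na(v) & v != floor(v))
    } else {
      which(!is.na(v) & !grepl("^\\s*-?[0-9]+\\s*$", as.character(v)))
    }
    if (length(bad) > 0) {
      stop(sprintf("column %s: non-integer event day at row(s) %s", col,
                   paste(utils::head(bad, 5), collapse = ", ")), call. = FALSE)
    }
    raw[[col]] <- as.integer(v)
  }
  raw$extubation_episodes <- dplyr::coalesce(as.character(raw$extubation_episodes), "")
  for (col in c("prior_pharmacotherapy", "pharmacotherapy_contraindicated",
                "ventilated_at_referral", "complex_chd",
                "bidirectional_or_r2l_flow", "major_anomaly", "tracheostomy")) {
    raw[[col]] <- as.logical(raw[[col]])
  }
  validate_registry(raw)
}

#' @rdname read_registry
#' @export
write_registry <- function(subjects, path) {
  validate_registry(subjects)
  params <- attr(subjects, "sim_params")
  header <- if (!is.null(params)) {
    sprintf("# ccwtrial registry (synthetic; seed %d)", params$seed)
  } else {
    "# ccwtrial registry"
  }
  readr::write_lines(header, path)
  readr::write_csv(subjects, path, append = TRUE, col_names = TRUE,
                   progress = FALSE)
  invisible(subjects)
}

#' Validate a registry table
#'
#' Checks the schema and the per-subject event-day invariants: event days
#' are non-negative integers; no recorded event follows the death day; and
#' extubation-episode days are strictly increasing.
#'
#' @param subjects Registry tibble.
#' @return The validated tibble, invisibly usable in a pipe.
#' @export
validate_registry <- function(subjects) {
  missing <- setdiff(registry_mandatory_cols, names(subjects))
  if (length(missing) > 0) {
    stop("registry is missing mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(subjects$subject_id)) {
    stop("duplicate subject_id values", call. = FALSE)
  }
  for (col in registry_event_cols) {
    v <- subjects[[col]]
    if (any(v[!is.na(v)] < 0)) {
      stop(sprintf("column %s: negative event day", col), call. = FALSE)
    }
  }
  ep <- episodes_table(subjects)
  if (nrow(ep) > 0) {
    bad_order <- ep |>
      dplyr::group_by(.data$subject_id) |>
      dplyr::filter(dplyr::n() > 1,
                    any(diff(.data$extubation_day) <= 0)) |>
      dplyr::ungroup()
    if (nrow(bad_order) > 0) {
      stop("extubation episode days not strictly increasing for subject(s): ",
           paste(unique(bad_order$subject_id), collapse = ", "),
           call. = FALSE)
    }
    with_death <- ep |>
      dplyr::left_join(dplyr::select(subjects, "subject_id", "death_day",
                                     "ltfu_day"),
                       by = "subject_id") |>
      dplyr::filter((!is.na(.data$death_day) &
                       .data$extubation_day >= .data$death_day) |
                      (!is.na(.data$ltfu_day) &
                         .data$extubation_day > .data$ltfu_day))
    if (nrow(with_death) > 0) {
      stop("extubation episode on/after death day (or after loss to ",
           "follow-up) for subject(s): ",
           paste(unique(with_death$subject_id), collapse = ", "),
           call. = FALSE)
    }
  }
  bad_int <- !is.na(subjects$intervention_day) & !is.na(subjects$death_day) &
    subjects$intervention_day > subjects$death_day
  if (any(bad_int)) {
    stop("intervention recorded after death for subject(s): ",
         paste(subjects$subject_id[bad_int], collapse = ", "), call. = FALSE)
  }
  subjects
}

#' Long table of extubation episodes
#'
#' Expands the packed `extubation_episodes` strings into one row per
#' episode.
#'
#' @param subjects Registry tibble.
#' @return Tibble `(subject_id, extubation_day, reintubated_within_7d)`.
#' @export
episodes_table <- function(subjects) {
  has <- !is.na(subjects$extubation_episodes) & subjects$extubation_episodes != ""
  if (!any(has)) {
    return(tibble::tibble(subject_id = character(0),
                          extubation_day = integer(0),
                          reintubated_within_7d = logical(0)))
  }
  tibble::tibble(subject_id = subjects$subject_id[has],
                 ep = subjects$extubation_episodes[has]) |>
    dplyr::mutate(ep = strsplit(.data$ep, ";", fixed = TRUE)) |>
    tidyr::unnest_longer("ep") |>
    tidyr::separate_wider_delim("ep", ":", names = c("extubation_day", "reint")) |>
    dplyr::mutate(extubation_day = as.integer(.data$extubation_day),
                  reintubated_within_7d = .data$reint == "1",
                  reint = NULL)
}

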
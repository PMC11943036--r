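#' Fit the pooled-logistic treatment-initiation model
#'
#' Discrete-time hazard model for initiating the definitive intervention on
#' day `t` given still untreated through `t - 1`, fitted by logistic
#' regression on subject-days at risk of initiation: days `0..max_day` on
#' which the subject is untreated, alive, still intubated (pre-outcome) and
#' under observation. Time enters as per-day indicator terms; days whose
#' stratum would be degenerate (no initiation, or no non-initiation, among
#' at-risk subject-days) are pooled with the following day(s) until every
#' bin contains both, a fallback that keeps the fit identified with short
#' grace periods.
#'
#' @param subjects Registry tibble with `outcome_day` (see
#'   [derive_outcomes()]).
#' @param covariates Character vector of adjustment covariates (columns of
#'   `subjects`). The default is the trial's baseline adjustment set: birth
#'   weight, gestational age, age at referral, sex, year of referral, and
#'   prior pharmacotherapy.
#' @param max_day Last day of the initiation risk period; use the largest
#'   grace-window end over the strategies being compared (14 for the default
#'   early/late pair).
#' @return An object of class `ccw_initiation_model` holding the covariate
#'   fit, the covariate-free (time-only) fit used as the stabilised-weight
#'   numerator, and the day-binning.
#' @export
#' @examples
#' reg <- derive_outcomes(simulate_registry(sim_params(n_subjects = 400, seed = 1)))
#' m <- fit_initiation_model(reg)
#' generics::glance(m)
fit_initiation_model <- function(subjects,
                                 covariates = default_covariates(),
                                 max_day = 14L) {
  missing_cov <- setdiff(covariates, names(subjects))
  if (length(missing_cov) > 0) {
    stop("covariate column(s) not in registry: ",
         paste(missing_cov, collapse = ", "), call. = FALSE)
  }
  if (!"outcome_day" %in% names(subjects)) {
    stop("run derive_outcomes() before fitting the initiation model",
         call. = FALSE)
  }
  rd <- initiation_risk_days(subjects, max_day)
  if (sum(rd$init) == 0L) {
    stop("no treatment-initiation events in the risk period; cannot fit ",
         "the initiation model", call. = FALSE)
  }
  bins <- pool_day_bins(rd, max_day)
  rd$day_bin <- bins$day_bin[match(rd$day, bins$day)]
  sidx <- match(rd$subject_id, subjects$subject_id)
  for (cv in covariates) rd[[cv]] <- subjects[[cv]][sidx]

  fml <- stats::as.formula(paste(
    "init ~ 0 + factor(day_bin)",
    if (length(covariates) > 0) paste("+", paste(covariates, collapse = " + "))
  ))
  fit <- stats::glm(fml, data = rd, family = stats::binomial())
  if (any(is.na(stats::coef(fit)))) {
    aliased <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("collinear covariates in the initiation model (aliased: ",
         paste(aliased, collapse = ", "), ")", call. = FALSE)
  }
  fv <- stats::fitted(fit)
  if (any(fv < 1e-8) || any(fv > 1 - 1e-8)) {
    stop("apparent perfect separation in the initiation model; ",
         "consider coarser day terms or fewer covariates", call. = FALSE)
  }
  # the covariate-free time model is saturated in the day bins, so its MLE
  # is the per-bin initiation proportion
  ev_bin <- rowsum(rd$init, rd$day_bin)
  n_bin <- rowsum(rep(1L, nrow(rd)), rd$day_bin)
  time_hazard <- as.numeric(ev_bin / n_bin)
  names(time_hazard) <- rownames(ev_bin)

  structure(
    list(type = "fitted", fit = fit, time_hazard_by_bin = time_hazard,
         day_bins = bins, covariates = covariates, max_day = as.integer(max_day),
         n_risk_days = nrow(rd), n_events = sum(rd$init)),
    class = "ccw_initiation_model"
  )
}

#' Default baseline adjustment set
#' @return Character vector of covariate column names.
#' @export
default_covariates <- function() {
  c("birth_weight_g", "gestational_age_weeks", "age_at_referral_days",
    "sex", "referral_year", "prior_pharmacotherapy")
}

#' Degenerate constant-hazard initiation model
#'
#' A stand-in initiation model whose predicted daily hazard is a known
#' constant, used to verify the weight bookkeeping against closed forms and
#' to supply weights when the initiation process is fully known.
#'
#' @param hazard Daily initiation probability, strictly in (0, 1).
#' @param max_day Last day of the initiation risk period.
#' @return A `ccw_initiation_model`.
#' @export
constant_initiation_model <- function(hazard, max_day = 14L) {
  stopifnot(is.numeric(hazard), length(hazard) == 1L,
            hazard > 0, hazard < 1)
  structure(
    list(type = "constant", hazard = hazard, max_day = as.integer(max_day)),
    class = "ccw_initiation_model"
  )
}

# subject-days at risk of initiation: untreated through the day, alive,
# pre-outcome, under observation, day <= max_day
initiation_risk_days <- function(subjects, max_day) {
  last <- pmin(
    max_day,
    dplyr::coalesce(subjects$intervention_day, .Machine$integer.max),
    dplyr::coalesce(subjects$outcome_day, .Machine$integer.max) - 1L,
    dplyr::coalesce(subjects$death_day, .Machine$integer.max) - 1L,
    dplyr::coalesce(subjects$ltfu_day, .Machine$integer.max) - 1L
  )
  keep <- last >= 0L
  ids <- subjects$subject_id[keep]
  last <- last[keep]
  n_rows <- last + 1L
  i <- rep.int(seq_along(ids), n_rows)
  day <- sequence(n_rows) - 1L
  int_day <- subjects$intervention_day[keep][i]
  tibble::tibble(subject_id = ids[i], day = day,
                 init = as.integer(!is.na(int_day) & int_day == day))
}

# Pool days 0..max_day into bins each containing at least one initiation
# and one non-initiation among at-risk rows; trailing incomplete bins merge
# backwards.
pool_day_bins <- function(rd, max_day) {
  per_day <- rd |>
    dplyr::group_by(.data$day) |>
    dplyr::summarise(n = dplyr::n(), ev = sum(.data$init), .groups = "drop") |>
    tidyr::complete(day = 0:max_day, fill = list(n = 0L, ev = 0L))
  bin <- integer(max_day + 1L)
  cur <- 1L
  ev_acc <- non_acc <- 0L
  for (d in 0:max_day) {
    bin[d + 1L] <- cur
    ev_acc <- ev_acc + per_day$ev[d + 1L]
    non_acc <- non_acc + (per_day$n[d + 1L] - per_day$ev[d + 1L])
    if (ev_acc > 0L && non_acc > 0L && d < max_day) {
      cur <- cur + 1L
      ev_acc <- non_acc <- 0L
    }
  }
  # last bin may be degenerate; merge it backwards
  if ((ev_acc == 0L || non_acc == 0L) && cur > 1L) {
    bin[bin == cur] <- cur - 1L
  }
  tibble::tibble(day = 0:max_day, day_bin = bin)
}

#' Predicted daily initiation hazards
#'
#' Evaluates the fitted initiation hazard for each subject on each requested
#' day, together with the covariate-free (time-only) hazard used as the
#' stabilised-weight numerator.
#'
#' @param model A `ccw_initiation_model`.
#' @param subjects Registry tibble with the model's covariates.
#' @param days Integer days (default `0:max_day`).
#' @return Tibble `(subject_id, day, hazard, hazard_time_only)`.
#' @export
initiation_hazard <- function(model, subjects, days = NULL) {
  stopifnot(inherits(model, "ccw_initiation_model"))
  if (is.null(days)) days <- 0:model$max_day
  days <- as.integer(days)
  hm <- init_hazard_matrix(model, subjects, days)
  nd <- length(days)
  tibble::tibble(
    subject_id = rep(subjects$subject_id, each = nd),
    day = rep(days, times = nrow(subjects)),
    hazard = as.vector(t(hm$H)),
    hazard_time_only = rep(hm$h0, times = nrow(subjects))
  )
}

# hazard matrix (subjects x days) plus the time-only hazard by day
init_hazard_matrix <- function(model, subjects, days) {
  ns <- nrow(subjects)
  nd <- length(days)
  if (model$type == "constant") {
    return(list(H = matrix(model$hazard, ns, nd),
                h0 = rep(model$hazard, nd)))
  }
  bin_of <- model$day_bins$day_bin[match(days, model$day_bins$day)]
  if (any(is.na(bin_of))) {
    stop("requested day outside the initiation model's risk period (0-",
         model$max_day, ")", call. = FALSE)
  }
  grid <- subjects[rep(seq_len(ns), each = nd),
                   model$covariates, drop = FALSE]
  grid$day_bin <- rep(bin_of, times = ns)
  p <- stats::predict(model$fit, newdata = grid, type = "response")
  h0 <- model$time_hazard_by_bin[as.character(bin_of)]
  list(H = matrix(p, ns, nd, byrow = TRUE), h0 = unname(h0))
}

#' @export
print.ccw_initiation_model <- function(x, ...) {
  if (x$type == "constant") {
    cat(sprintf("<ccw_initiation_model> constant hazard %.4g (days 0-%d)\n",
                x$hazard, x$max_day))
  } else {
    cat(sprintf("<ccw_initiation_model> pooled logistic, %d subject-days, %d initiations, days 0-%d in %d bin(s)\n",
                x$n_risk_days, x$n_events, x$max_day, max(x$day_bins$day_bin)))
  }
  invisible(x)
}

#' @export
tidy.ccw_initiation_model <- function(x, ...) {
  if (x$type == "constant") {
    return(tibble::tibble(term = "hazard", estimate = x$hazard,
                          std.error = NA_real_, statistic = NA_real_,
                          p.value = NA_real_))
  }
  s <- stats::coef(summary(x$fit))
  tibble::tibble(term = rownames(s), estimate = s[, 1], std.error = s[, 2],
                 statistic = s[, 3], p.value = s[, 4])
}

#' @export
glance.ccw_initiation_model <- function(x, ...) {
  if (x$type == "constant") {
    return(tibble::tibble(type = "constant", n_risk_days = NA_integer_,
                          n_events = NA_integer_, n_day_bins = NA_integer_,
                          deviance = NA_real_))
  }
  tibble::tibble(type = "fitted", n_risk_days = x$n_risk_days,
                 n_events = x$n_events, n_day_bins = max(x$day_bins$day_bin),
                 deviance = stats::deviance(x$fit))
}
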
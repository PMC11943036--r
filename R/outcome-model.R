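#' Weighted pooled-logistic outcome model
#'
#' Discrete-time hazard model for successful extubation fitted on weighted
#' clone-day rows. The model is marginal — strategy, time, and their
#' interaction only — because confounding is handled entirely by the
#' inverse-probability weights. Clone-days are first aggregated to
#' (strategy, day) cells with weight totals, which leaves the weighted
#' binomial likelihood unchanged and makes the fit cheap regardless of
#' cohort size.
#'
#' Rows flagged `artificial_censor` are excluded (the clone leaves the risk
#' set at deviation); rows after death are retained under the total-effect
#' convention, so deaths depress the hazard rather than the risk set.
#'
#' @param clone_days Clone-day table from [expand_person_days()].
#' @param weights Optional weight table from [compute_weights()] aligned by
#'   `(clone_id, day)`; `NULL` fits unweighted (weights identically 1).
#' @param time_spec `"cubic"` — logit hazard cubic in day with full
#'   strategy interactions — or `"saturated"` — one free hazard per
#'   (strategy, day) cell, computed in closed form as the weighted event
#'   proportion (the exact maximum-likelihood fit of the saturated model).
#' @param weight_col Which weight to use, `"sw"` (stabilised, default) or
#'   `"w"`.
#' @param horizon Last follow-up day for prediction.
#' @return An object of class `ccw_outcome_model` with the per-day fitted
#'   hazards for each strategy.
#' @export
fit_outcome_model <- function(clone_days, weights = NULL,
                              time_spec = c("cubic", "saturated"),
                              weight_col = c("sw", "w"),
                              horizon = 45L) {
  time_spec <- match.arg(time_spec)
  weight_col <- match.arg(weight_col)
  horizon <- as.integer(horizon)

  if (is.null(weights)) {
    w_all <- rep(1, nrow(clone_days))
  } else if (nrow(weights) == nrow(clone_days) &&
             identical(weights$clone_id, clone_days$clone_id) &&
             identical(weights$day, clone_days$day)) {
    w_all <- weights[[weight_col]]   # aligned row-for-row, skip the join
  } else {
    j <- dplyr::left_join(
      dplyr::select(clone_days, "clone_id", "day"),
      dplyr::select(weights, "clone_id", "day",
                    .w = dplyr::all_of(weight_col)),
      by = c("clone_id", "day")
    )
    if (any(is.na(j$.w))) {
      stop("weight table does not cover every clone-day row", call. = FALSE)
    }
    w_all <- j$.w
  }
  keep <- clone_days$artificial_censor == 0L
  dat <- clone_days[keep, c("strategy", "day", "event")]
  dat$.w <- w_all[keep]

  key <- paste(dat$strategy, dat$day, sep = "\r")
  agg <- rowsum(cbind(dat$.w, dat$.w * dat$event), key)
  kp <- strsplit(rownames(agg), "\r", fixed = TRUE)
  cells <- tibble::tibble(
    strategy = vapply(kp, `[`, character(1), 1L),
    day = as.integer(vapply(kp, `[`, character(1), 2L)),
    n_w = unname(agg[, 1L]),
    ev_w = unname(agg[, 2L])
  ) |>
    dplyr::filter(.data$n_w > 0) |>
    dplyr::arrange(.data$strategy, .data$day)

  strat_levels <- unique(clone_days$strategy)
  grid <- tidyr::crossing(strategy = strat_levels, day = 0:horizon)

  if (time_spec == "saturated") {
    hazards <- grid |>
      dplyr::left_join(dplyr::mutate(cells, haz = .data$ev_w / .data$n_w),
                       by = c("strategy", "day")) |>
      dplyr::mutate(haz = dplyr::coalesce(.data$haz, 0)) |>
      dplyr::select("strategy", "day", "haz")
    fit <- NULL
  } else {
    cells$prop <- cells$ev_w / cells$n_w
    X <- outcome_design(cells$strategy, cells$day, strat_levels, horizon)
    fit <- suppressWarnings(
      stats::glm.fit(X, cells$prop, weights = cells$n_w,
                     family = stats::quasibinomial())
    )
    if (!fit$converged) {
      stop("outcome model did not converge (",
           nrow(cells), " cells, ", sum(cells$ev_w > 0), " with events)",
           call. = FALSE)
    }
    Xg <- outcome_design(grid$strategy, grid$day, strat_levels, horizon)
    grid$haz <- as.numeric(stats::plogis(Xg %*% fit$coefficients))
    hazards <- grid[, c("strategy", "day", "haz")]
  }

  structure(
    list(type = time_spec, fit = fit, hazards = hazards, cells = cells,
         horizon = horizon, weight_col = if (is.null(weights)) "none" else weight_col),
    class = "ccw_outcome_model"
  )
}

#' Cumulative-incidence curves from a fitted outcome model
#'
#' Builds each strategy's cumulative incidence from the fitted day-specific
#' hazards: `CI(t) = 1 - prod_(k<=t) (1 - h(k))`. The hazard of day `t`
#' applies to the interval `[t, t + 1)` and `CI(t)` is the risk by the end
#' of day `t`, so day 0 events are included in `CI(0)`.
#'
#' @param model A `ccw_outcome_model`.
#' @return Tibble `(strategy, day, haz, cum_inc)` for days `0:horizon`,
#'   with `cum_inc` non-decreasing within strategy.
#' @export
risk_curves <- function(model) {
  stopifnot(inherits(model, "ccw_outcome_model"))
  hz <- model$hazards[order(model$hazards$strategy, model$hazards$day), ]
  # hazards hold one contiguous day block per strategy after ordering
  ls <- log1p(-hz$haz)
  cs <- cumsum(ls)
  first <- !duplicated(hz$strategy)
  base <- (cs - ls)[first]
  hz$cum_inc <- 1 - exp(cs - base[cumsum(first)])
  hz
}

# design matrix of the cubic time specification: intercept, strategy
# dummies, scaled day polynomial, and their interactions
outcome_design <- function(strategy, day, levels, horizon) {
  d <- day / horizon
  base <- cbind(1, d, d^2, d^3)
  colnames(base) <- c("(Intercept)", "day", "day2", "day3")
  out <- base
  for (lev in levels[-1]) {
    s <- as.numeric(strategy == lev)
    blk <- base * s
    colnames(blk) <- paste0("strategy", lev,
                            c("", ":day", ":day2", ":day3"))
    out <- cbind(out, blk)
  }
  out
}

#' @export
print.ccw_outcome_model <- function(x, ...) {
  cat(sprintf("<ccw_outcome_model> %s time specification, weights: %s, %d (strategy, day) cells\n",
              x$type, x$weight_col, nrow(x$cells)))
  invisible(x)
}

#' Coefficients of the outcome model
#'
#' Point estimates only: model-based standard errors are not meaningful
#' under inverse-probability weighting of dependent clones, so interval
#' estimation is delegated to the subject-level bootstrap
#' ([ccw_bootstrap()]).
#'
#' @param x A `ccw_outcome_model`.
#' @param ... Unused.
#' @return For the cubic specification, a tibble `(term, estimate)`; for
#'   the saturated one, the per-(strategy, day) hazard estimates.
#' @export
tidy.ccw_outcome_model <- function(x, ...) {
  if (x$type == "saturated") {
    return(dplyr::rename(x$hazards, estimate = "haz"))
  }
  tibble::tibble(term = names(x$fit$coefficients),
                 estimate = unname(x$fit$coefficients))
}

#' @export
glance.ccw_outcome_model <- function(x, ...) {
  tibble::tibble(type = x$type, weights = x$weight_col,
                 n_cells = nrow(x$cells), horizon = x$horizon)
}
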
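#' Subject-level bootstrap confidence bands
#'
#' Percentile bootstrap for the cumulative-incidence curves, risk
#' differences and mean ventilator days. Resampling is always at the
#' subject level — each replicate draws eligible subjects with replacement
#' and regenerates clones, censoring, weights and the outcome model from
#' scratch — because the two clones of one subject are dependent by
#' construction. Replicates that fail (e.g. non-convergence or a positivity
#' violation in a degenerate resample) are logged and skipped; more than
#' 10% failures aborts with a diagnostic.
#'
#' @param registry Registry tibble or CSV path.
#' @param n_boot Number of bootstrap replicates.
#' @param seed Integer seed; fixed seed gives identical bands.
#' @param level Confidence level (default 0.95, percentile method).
#' @param ... Pipeline options passed to [ccw_emulate()] (strategies,
#'   covariates, time_spec, estimand, ...).
#' @return An object of class `ccw_boot`: the point-estimate `fit`
#'   (a `ccw_fit`), plus `curve_bands` `(strategy, day, cum_inc, lo, hi)`,
#'   `rd_bands`, `mvd_bands`, and the replicate log.
#' @export
#' @examples
#' reg <- simulate_registry(sim_params(n_subjects = 150, seed = 21))
#' bt <- ccw_bootstrap(reg, n_boot = 20, seed = 1)
#' dplyr::filter(bt$rd_bands, day == 45)
ccw_bootstrap <- function(registry, n_boot = 500L, seed = 1L, level = 0.95,
                          ...) {
  stopifnot(is_count(n_boot))
  if (is.character(registry) && length(registry) == 1L) {
    registry <- read_registry(registry)
  }
  fit <- ccw_emulate(registry, ...)
  s <- fit$settings
  eligible <- derive_outcomes(fit$eligibility$eligible, horizon = s$horizon)
  ref <- fit$effects$ref
  n <- nrow(eligible)

  set.seed(as.integer(seed))
  idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)

  # replicate curves are collected as columns of a matrix over the fixed
  # (strategy, day) grid of the point fit
  grid <- dplyr::select(fit$curves, "strategy", "day")
  grid_key <- paste(grid$strategy, grid$day)
  curve_mat <- matrix(NA_real_, nrow(grid), n_boot)
  failures <- character(0)
  for (b in seq_len(n_boot)) {
    boot_subjects <- eligible[idx[, b], , drop = FALSE]
    boot_subjects$subject_id <- sprintf("B%05d", seq_len(n))
    cv <- tryCatch(
      ccw_core(boot_subjects, s$strategies, s$covariates, s$time_spec,
               s$weighting, s$estimand, s$truncation, s$weight_col,
               s$horizon)$curves,
      error = function(e) {
        failures <<- c(failures, conditionMessage(e))
        NULL
      })
    if (!is.null(cv)) {
      curve_mat[, b] <- cv$cum_inc[match(grid_key, paste(cv$strategy, cv$day))]
    }
  }
  ok <- !is.na(curve_mat[1L, ])
  if (sum(!ok) > 0.10 * n_boot) {
    stop(sprintf("bootstrap aborted: %d of %d replicates failed (first: %s)",
                 sum(!ok), n_boot, failures[1]), call. = FALSE)
  }
  curve_mat <- curve_mat[, ok, drop = FALSE]

  alpha <- (1 - level) / 2
  qrow <- function(m) t(apply(m, 1L, stats::quantile, probs = c(alpha, 1 - alpha),
                              names = FALSE))

  cb <- qrow(curve_mat)
  curve_bands <- dplyr::bind_cols(fit$curves[, c("strategy", "day", "cum_inc")],
                                  tibble::tibble(lo = cb[, 1], hi = cb[, 2]))

  # risk differences and mean ventilator days per replicate, from the grid
  ref_rows <- grid$strategy == ref
  ref_order <- match(grid$day[!ref_rows], grid$day[ref_rows])
  rd_mat <- curve_mat[!ref_rows, , drop = FALSE] -
    curve_mat[ref_rows, , drop = FALSE][ref_order, , drop = FALSE]
  rb <- qrow(rd_mat)
  rd_bands <- fit$effects$rd |>
    dplyr::bind_cols(tibble::tibble(lo = rb[, 1], hi = rb[, 2]))

  mvd_rows <- grid$day >= 1 & grid$day <= s$horizon
  mvd_mat <- rowsum(1 - curve_mat[mvd_rows, , drop = FALSE],
                    grid$strategy[mvd_rows])
  mvd_diff_mat <- sweep(mvd_mat, 2L, mvd_mat[ref, ])
  mb <- qrow(mvd_mat)
  db <- qrow(mvd_diff_mat)
  mvd_bands <- fit$effects$mean_vent_days |>
    dplyr::left_join(
      tibble::tibble(strategy = rownames(mvd_mat),
                     lo = mb[, 1], hi = mb[, 2],
                     lo_diff = db[, 1], hi_diff = db[, 2]),
      by = "strategy") |>
    dplyr::select("strategy", "mean_vent_days", "lo", "hi",
                  "diff_vs_ref", "lo_diff", "hi_diff")

  structure(
    list(fit = fit, curve_bands = curve_bands, rd_bands = rd_bands,
         mvd_bands = mvd_bands, n_boot = n_boot, n_failed = sum(!ok),
         failures = failures, seed = as.integer(seed), level = level),
    class = "ccw_boot"
  )
}

#' @export
print.ccw_boot <- function(x, ...) {
  cat(sprintf("<ccw_boot> %d replicates (%d failed), %.0f%% percentile intervals, seed %d\n",
              x$n_boot, x$n_failed, 100 * x$level, x$seed))
  sel <- x$fit$effects$selected_days
  print(dplyr::filter(x$rd_bands, .data$day %in% sel))
  invisible(x)
}

#' @export
tidy.ccw_boot <- function(x, ...) x$curve_bands

#' @export
glance.ccw_boot <- function(x, ...) {
  horizon <- x$fit$settings$horizon
  rd45 <- dplyr::filter(x$rd_bands, .data$day == horizon)
  tibble::tibble(n_boot = x$n_boot, n_failed = x$n_failed, level = x$level,
                 rd_end = rd45$rd[1], rd_end_lo = rd45$lo[1],
                 rd_end_hi = rd45$hi[1])
}
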
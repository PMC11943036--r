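#' Inverse-probability-of-adherence weights for clone-days
#'
#' Converts the initiation model into day-by-day uncensoring probabilities
#' under the deadline form of the clone-censor-weight scheme and returns
#' their cumulative inverse per clone-day. For a clone with grace window
#' `[s, e]` on the referral clock:
#'
#' * each day `k < s` on which the subject is untreated and at risk of
#'   initiating contributes a factor `1 / (1 - h(k | L))` (the clone stays
#'   uncensored only by *not* initiating early);
#' * days `s..e-1` carry no censoring risk and contribute 1;
#' * a clone still untreated entering day `e` stays uncensored only by
#'   initiating that day, contributing `1 / h(e | L)`;
#' * weights are frozen after the window, and factors stop accruing once
#'   the subject is no longer at risk of initiation (event, death, or loss
#'   to follow-up), since no censoring risk remains.
#'
#' The running product is the unstabilised weight `w`. The stabilised
#' weight `sw` multiplies `w` by the marginal probability, under the
#' covariate-free time-only initiation model, of remaining uncensored
#' through the day — a factor shared by every clone of a strategy at a
#' given day. This rescales `sw` towards mean 1 without altering relative
#' weights within any (strategy, day) stratum, so risk curves estimated
#' with `sw` and `w` coincide whenever the outcome model is saturated in
#' strategy and time. Both are truncated at the given quantile of their
#' distribution over clone-day rows (truncated rows are flagged).
#'
#' @param clone_days Clone-day table from [expand_person_days()].
#' @param clones Clone table from [make_clones()] (supplies windows and
#'   event days).
#' @param subjects Registry tibble (supplies model covariates).
#' @param model A [fit_initiation_model()] or [constant_initiation_model()]
#'   object.
#' @param truncation Quantile in (0, 1] at which weights are capped
#'   (default 0.99); `1` disables truncation.
#' @return Tibble `(clone_id, strategy, day, w, sw, truncated)` aligned
#'   row-for-row with `clone_days`, with a diagnostics list attached as
#'   attribute `"diagnostics"` (min/max hazard by day among used factors,
#'   truncation counts).
#' @export
compute_weights <- function(clone_days, clones, subjects, model,
                            truncation = 0.99) {
  stopifnot(inherits(model, "ccw_initiation_model"))
  if (!is.numeric(truncation) || truncation <= 0 || truncation > 1) {
    stop("truncation must be in (0, 1]", call. = FALSE)
  }
  max_e <- max(clones$ref_end)
  if (model$max_day < max_e) {
    stop("initiation model risk period (0-", model$max_day,
         ") is shorter than the largest grace window end (", max_e, ")",
         call. = FALSE)
  }
  hm <- init_hazard_matrix(model, subjects, 0:max_e)

  ci <- match(clone_days$clone_id, clones$clone_id)
  si <- match(clones$subject_id, subjects$subject_id)[ci]
  day <- clone_days$day
  n <- length(day)
  if (n > 1L) {
    d_ci <- diff(ci)
    if (any(d_ci < 0L) || any(d_ci == 0L & diff(day) != 1L)) {
      stop("clone_days must be ordered by clone with contiguous days ",
           "(as produced by expand_person_days)", call. = FALSE)
    }
  }

  rs <- clones$ref_start[ci]
  re <- clones$ref_end[ci]
  int <- clones$intervention_day[ci]
  stop_k <- pmin(dplyr::coalesce(clones$outcome_day, .Machine$integer.max),
                 dplyr::coalesce(clones$death_day, .Machine$integer.max),
                 dplyr::coalesce(clones$ltfu_day, .Machine$integer.max))[ci]

  in_grid <- day <= max_e
  h <- rep(NA_real_, n)
  h[in_grid] <- hm$H[cbind(si[in_grid], day[in_grid] + 1L)]

  untreated_pre <- is.na(int) | day < int | int >= rs
  use_pre <- day < stop_k & day < rs & untreated_pre
  use_spike <- day < stop_k & day == re & !is.na(int) & int == re

  # positivity: pre-window factors need h < 1, the deadline spike needs h > 0
  eps <- 1e-8
  bad <- (use_pre & h >= 1 - eps) | (use_spike & h <= eps)
  if (any(bad)) {
    ex <- utils::head(unique(sprintf("%s day %d (h=%.3g)",
                                     clone_days$subject_id[bad], day[bad],
                                     h[bad])), 5)
    stop("positivity violation: estimated initiation hazard at the boundary ",
         "for ", sum(bad), " clone-day(s), e.g. ",
         paste(ex, collapse = "; "), call. = FALSE)
  }

  f <- rep(1, n)
  f[use_pre] <- 1 / (1 - h[use_pre])
  f[use_spike] <- 1 / h[use_spike]

  # marginal stabilisation factor: the time-only model's probability terms
  # for remaining uncensored given the clone's window, applied to every row
  wkey <- paste(clones$ref_start, clones$ref_end)
  uk <- which(!duplicated(wkey))
  p_win_u <- mapply(function(s, e) 1 - prod(1 - hm$h0[(s:e) + 1L]),
                    clones$ref_start[uk], clones$ref_end[uk])
  p_win <- p_win_u[match(wkey, wkey[uk])]
  fn <- rep(1, n)
  pre_n <- day < rs
  fn[pre_n] <- 1 - hm$h0[day[pre_n] + 1L]
  at_e <- day == re
  fn[at_e] <- p_win[ci[at_e]]

  # grouped cumulative products over contiguous clone blocks
  new_grp <- c(TRUE, ci[-1L] != ci[-n])
  grp <- cumsum(new_grp)
  cum_grp <- function(lf) {
    s <- cumsum(lf)
    base <- (s - lf)[new_grp]
    exp(s - base[grp])
  }
  w <- cum_grp(log(f))
  sw <- w * cum_grp(log(fn))

  used <- use_pre | use_spike
  diagnostics <- list(
    hazard_by_day = tibble::tibble(day = day[used], hazard = h[used]) |>
      dplyr::group_by(.data$day) |>
      dplyr::summarise(n_factors = dplyr::n(),
                       min_hazard = min(.data$hazard),
                       max_hazard = max(.data$hazard), .groups = "drop")
  )

  truncated <- rep(FALSE, n)
  if (truncation < 1) {
    cap_w <- stats::quantile(w, truncation, names = FALSE)
    cap_sw <- stats::quantile(sw, truncation, names = FALSE)
    truncated <- w > cap_w | sw > cap_sw
    w <- pmin(w, cap_w)
    sw <- pmin(sw, cap_sw)
    diagnostics$truncation <- list(quantile = truncation, cap_w = cap_w,
                                   cap_sw = cap_sw,
                                   n_truncated = sum(truncated))
  } else {
    diagnostics$truncation <- list(quantile = 1, n_truncated = 0L)
  }

  out <- tibble::tibble(clone_id = clone_days$clone_id,
                        strategy = clone_days$strategy,
                        day = day, w = w, sw = sw, truncated = truncated)
  attr(out, "diagnostics") <- diagnostics
  out
}

#' Weight diagnostics text report
#'
#' Summarises the positivity surface (min/max fitted initiation hazard on
#' the days where weight factors are used) and the truncation applied.
#'
#' @param weights Weight table from [compute_weights()].
#' @return Character vector of report lines.
#' @export
weight_diagnostics <- function(weights) {
  d <- attr(weights, "diagnostics")
  if (is.null(d)) stop("weights carry no diagnostics attribute", call. = FALSE)
  lines <- c("inverse-probability weight diagnostics",
             sprintf("clone-day rows: %d; mean w: %.4f; mean sw: %.4f; max w: %.3f",
                     nrow(weights), mean(weights$w), mean(weights$sw),
                     max(weights$w)),
             "fitted initiation hazard where weight factors apply:")
  hb <- d$hazard_by_day
  lines <- c(lines, sprintf("  day %2d: n=%5d  min=%.4f  max=%.4f",
                            hb$day, hb$n_factors, hb$min_hazard, hb$max_hazard))
  tr <- d$truncation
  lines <- c(lines,
             if (tr$quantile < 1) {
               sprintf("truncation at quantile %.3f: %d row(s) capped (w cap %.3f, sw cap %.3f)",
                       tr$quantile, tr$n_truncated, tr$cap_w, tr$cap_sw)
             } else {
               "truncation: none"
             })
  lines
}
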
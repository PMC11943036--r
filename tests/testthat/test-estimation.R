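# uncensored fixture: every intervention inside one wide window, no loss to
# follow-up, so no clone is ever artificially censored
uncensored_registry <- function(n = 60, seed = 41, p_death = 0.1) {
  set.seed(seed)
  rows <- lapply(seq_len(n), function(i) {
    int <- sample(0:4, 1)
    death <- if (runif(1) < p_death) sample(6:44, 1) else NA_integer_
    out_day <- if (runif(1) < 0.7) sample(1:44, 1) else NA_integer_
    if (!is.na(death) && !is.na(out_day) && out_day >= death) out_day <- NA_integer_
    eps <- if (!is.na(out_day)) sprintf("%d:0", out_day) else ""
    make_subject(sprintf("u%03d", i), intervention_day = int,
                 extubation_episodes = eps, death_day = death)
  })
  dplyr::bind_rows(rows)
}

test_that("the saturated fit reproduces empirical day-specific proportions", {
  reg <- derive_outcomes(uncensored_registry())
  cl <- make_clones(reg, strategy("all", 0, 4))
  cd <- expand_person_days(cl)
  m <- fit_outcome_model(cd, weights = NULL, time_spec = "saturated")
  emp <- dplyr::summarise(
    dplyr::group_by(cd[cd$artificial_censor == 0, ], .data$day),
    haz = mean(.data$event), .groups = "drop")
  got <- m$hazards[m$hazards$day %in% emp$day, ]
  expect_equal(got$haz, emp$haz, tolerance = 1e-12)
})

test_that("risk curves follow the hazard-stacking closed form", {
  # constant hazard 0.05: CI(14) = 1 - 0.95^15 over days 0..14
  mdl <- structure(
    list(type = "saturated", fit = NULL,
         hazards = tibble::tibble(strategy = "s", day = 0:45, haz = 0.05),
         cells = NULL, horizon = 45L, weight_col = "none"),
    class = "ccw_outcome_model")
  rc <- risk_curves(mdl)
  expect_equal(rc$cum_inc[rc$day == 14], 1 - 0.95^15, tolerance = 1e-12)
  expect_equal(rc$cum_inc[rc$day == 0], 0.05, tolerance = 1e-12)
  mdl$hazards$haz <- 0
  expect_true(all(risk_curves(mdl)$cum_inc == 0))
})

test_that("two strategies with identical hazards estimate a null contrast", {
  reg <- simulate_registry(sim_preset("null_effect", n_subjects = 4000,
                                      seed = 42))
  fit <- ccw_emulate(reg, truncation = 1)
  # max over 46 daily contrasts, so allow for the maximum of the noise
  expect_lt(max(abs(fit$effects$rd$rd)), 0.04)
  expect_lt(abs(fit$effects$rd$rd[fit$effects$rd$day == 45]), 0.03)
})

test_that("mean ventilator days matches its arithmetic identities", {
  mk <- function(ci) tibble::tibble(strategy = "s", day = 0:45, cum_inc = ci)
  expect_equal(mean_ventilator_days(mk(rep(0, 46)))$mean_vent_days, 45)
  expect_equal(mean_ventilator_days(mk(c(0, rep(1, 45))))$mean_vent_days, 0)
  expect_equal(mean_ventilator_days(mk((0:45) / 45))$mean_vent_days, 22)
})

test_that("the effect report is exactly the curve arithmetic", {
  reg <- simulate_registry(sim_preset("default", n_subjects = 400, seed = 43))
  fit <- ccw_emulate(reg)
  cv <- fit$curves
  rd45 <- fit$effects$rd$rd[fit$effects$rd$day == 45]
  expect_equal(rd45,
               cv$cum_inc[cv$strategy == "early" & cv$day == 45] -
                 cv$cum_inc[cv$strategy == "late" & cv$day == 45])
  mvd <- fit$effects$mean_vent_days
  expect_equal(mvd$mean_vent_days[mvd$strategy == "early"],
               sum(1 - cv$cum_inc[cv$strategy == "early" & cv$day >= 1]))
})

test_that("baseline table is weight-scale invariant and exact on a fixture", {
  el <- derive_outcomes(make_registry(
    make_subject("a", birth_weight_g = 500, intervention_day = 1L),
    make_subject("b", birth_weight_g = 600, intervention_day = 2L),
    make_subject("c", birth_weight_g = 700, intervention_day = 3L),
    make_subject("d", birth_weight_g = 800, intervention_day = 4L),
    make_subject("e", birth_weight_g = 900, intervention_day = 4L)
  ))
  cl <- make_clones(el, default_strategies())
  # unit weights: weighted column equals unweighted
  bt1 <- baseline_table(cl, weights = NULL, subjects = el)
  expect_equal(bt1$unweighted[bt1$variable != "n"],
               bt1$weighted[bt1$variable != "n"])
  # hand-computed weighted median: weights (1,1,1,5,5) on 500..900
  wt <- expand_person_days(cl)
  wt <- tibble::tibble(clone_id = wt$clone_id, strategy = wt$strategy,
                       day = wt$day,
                       w = ifelse(wt$subject_id %in% c("d", "e"), 5, 1),
                       sw = 1, truncated = FALSE)
  bt2 <- baseline_table(cl, weights = wt, subjects = el, weight_col = "w")
  bw_row <- bt2[bt2$variable == "birth_weight_g, median [IQR]" &
                  bt2$strategy == "early", ]
  expect_match(bw_row$weighted, "^800")
  expect_match(bw_row$unweighted, "^700")
  # doubling all weights changes medians and percentages (not the pseudo-n)
  wt3 <- dplyr::mutate(wt, w = 2 * w)
  bt3 <- baseline_table(cl, weights = wt3, subjects = el, weight_col = "w")
  keep <- bt2$variable != "n"
  expect_equal(bt3$weighted[keep], bt2$weighted[keep])
})

test_that("weighted quantiles agree with direct expansion", {
  x <- c(3, 1, 4, 1, 5)
  w <- c(2, 1, 3, 1, 1)
  # inverse-CDF definition: smallest x whose cumulative weight reaches p
  expect_equal(weighted_quantile(x, w, 0.5),
               stats::quantile(rep(x, times = w), 0.5, type = 1,
                               names = FALSE))
  expect_equal(weighted_quantile(1:5, rep(1, 5), c(0.25, 0.75)), c(2, 4))
  expect_error(weighted_quantile(1:3, c(-1, 1, 1)), "non-negative")
})

test_that("total effect and controlled direct effect coincide without deaths", {
  reg <- simulate_registry(flat_params(400, seed = 44, init_h = 0.2,
                                       ext_intercept = -3.2, treated = 0.8,
                                       death = 0, ltfu = 0.01, reint = 0.3))
  f_tot <- ccw_emulate(reg, estimand = "total")
  f_cde <- run_cde_variant(reg)
  expect_identical(f_tot$curves, f_cde$curves)
  expect_identical(f_tot$effects$rd, f_cde$effects$rd)
  # deaths strictly after the horizon are equally inert
  reg2 <- reg
  reg2$death_day[1:5] <- 50L
  expect_identical(ccw_emulate(reg2, estimand = "total")$curves,
                   ccw_emulate(reg2, estimand = "cde")$curves)
})

test_that("censoring deaths raises the cumulative incidence", {
  reg <- simulate_registry(flat_params(2500, seed = 45, init_h = 0.2,
                                       ext_intercept = -3.4, treated = 0.6,
                                       death = 0.012, ltfu = 0, reint = 0.3))
  f_tot <- ccw_emulate(reg, estimand = "total", truncation = 1)
  f_cde <- ccw_emulate(reg, estimand = "cde", truncation = 1)
  cmp <- dplyr::left_join(f_cde$curves, f_tot$curves,
                          by = c("strategy", "day"),
                          suffix = c("_cde", "_tot"))
  cmp <- cmp[cmp$day >= 10, ]  # differences accumulate with deaths
  expect_true(all(cmp$cum_inc_cde >= cmp$cum_inc_tot - 0.01))
  expect_gt(max(cmp$cum_inc_cde - cmp$cum_inc_tot), 0.02)
})

test_that("an irrelevant extra covariate leaves the estimate unchanged", {
  reg <- simulate_registry(sim_preset("sites", n_subjects = 2500, seed = 46))
  f_main <- ccw_emulate(reg, truncation = 1)
  f_site <- run_covariate_variant(reg, "referral_site", truncation = 1)
  d45 <- abs(f_site$curves$cum_inc[f_site$curves$day == 45] -
               f_main$curves$cum_inc[f_main$curves$day == 45])
  expect_lt(max(d45), 0.03)
  expect_error(run_covariate_variant(reg, "no_such_col"), "no_such_col")
})
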
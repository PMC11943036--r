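test_that("a constant simulated hazard is recovered by the initiation model", {
  reg <- derive_outcomes(simulate_registry(
    flat_params(4000, seed = 21, init_h = 0.2, ext_intercept = -40)))
  m <- fit_initiation_model(reg)
  hz <- initiation_hazard(m, reg[1:5, ])
  expect_equal(mean(hz$hazard), 0.2, tolerance = 0.02)
  expect_true(all(hz$hazard > 0 & hz$hazard < 1))
  expect_equal(glance(m)$n_events,
               sum(!is.na(reg$intervention_day) & reg$intervention_day <= 14))
})

test_that("null and confounded covariate effects are recovered in sign", {
  # no covariate effects: birth-weight coefficient near zero within its CI
  reg0 <- derive_outcomes(simulate_registry(
    flat_params(3000, seed = 22, init_h = 0.2, ext_intercept = -40)))
  m0 <- fit_initiation_model(reg0)
  co <- tidy(m0)
  bw0 <- co[co$term == "birth_weight_g", ]
  expect_lt(abs(bw0$estimate), 2.5 * bw0$std.error + 1e-12)

  # confounded preset: lower birth weight raises the initiation hazard
  reg1 <- derive_outcomes(simulate_registry(
    sim_preset("confounded_strong", n_subjects = 3000, seed = 23)))
  m1 <- fit_initiation_model(reg1)
  bw1 <- tidy(m1)[tidy(m1)$term == "birth_weight_g", ]
  expect_lt(bw1$estimate, 0)
  expect_gt(abs(bw1$estimate / bw1$std.error), 2)
})

test_that("the initiation model surfaces degenerate inputs", {
  reg <- derive_outcomes(simulate_registry(
    sim_preset("default", n_subjects = 400, seed = 24)))
  reg$bw_copy <- reg$birth_weight_g
  expect_error(
    fit_initiation_model(reg, covariates = c(default_covariates(), "bw_copy")),
    "collinear")
  expect_error(fit_initiation_model(reg, covariates = "no_such_column"),
               "no_such_column")
  reg_none <- reg
  reg_none$intervention_day <- NA_integer_
  expect_error(fit_initiation_model(reg_none), "no treatment-initiation")
})

test_that("day pooling keeps every bin identified", {
  # interventions only on days 0-2: later day strata have no events and
  # must be pooled rather than fitted
  reg <- derive_outcomes(make_registry(
    make_subject("a", intervention_day = 0L),
    make_subject("b", intervention_day = 1L),
    make_subject("c", intervention_day = 2L),
    make_subject("d"), make_subject("e")
  ))
  m <- fit_initiation_model(reg, covariates = character(0))
  hz <- initiation_hazard(m, reg)
  expect_true(all(hz$hazard > 0 & hz$hazard < 1))
})

test_that("weights match their closed forms under a constant hazard", {
  el <- derive_outcomes(make_registry(
    make_subject("t2", intervention_day = 2L),
    make_subject("t4", intervention_day = 4L),
    make_subject("t6", intervention_day = 6L)
  ))
  cl <- make_clones(el, default_strategies())
  cd <- expand_person_days(cl)
  wt <- compute_weights(cd, cl, el, constant_initiation_model(0.2),
                        truncation = 1)
  w_at <- function(id, d) wt$w[wt$clone_id == id & wt$day == d]
  # treated inside the window before the deadline: no censoring risk realised
  expect_equal(w_at("t2.early", 45), 1, tolerance = 1e-12)
  # early deadline initiator: 1/h from day 4 onward
  expect_equal(w_at("t4.early", 4), 5, tolerance = 1e-12)
  expect_equal(w_at("t4.early", 45), 5, tolerance = 1e-12)
  # late clone surviving the early window untreated: (1/(1-h))^5
  expect_equal(w_at("t6.late", 4), (1 / 0.8)^5, tolerance = 1e-12)
  # frozen after the window
  expect_equal(w_at("t6.late", 45), (1 / 0.8)^5, tolerance = 1e-12)
  # weights are 1 wherever no censoring risk exists
  expect_true(all(wt$w[wt$strategy == "early" & wt$day < 4] == 1))
})

test_that("weights stop accruing at death and at loss to follow-up", {
  el <- derive_outcomes(make_registry(
    make_subject("dead2", death_day = 2L),
    make_subject("lt3", intervention_day = 1L, ltfu_day = 3L)
  ))
  cl <- make_clones(el, default_strategies())
  cd <- expand_person_days(cl)
  wt <- compute_weights(cd, cl, el, constant_initiation_model(0.2),
                        truncation = 1)
  # late clone dead on day 2: only days 0 and 1 contribute pre-window factors
  expect_equal(wt$w[wt$clone_id == "dead2.late" & wt$day == 45],
               (1 / 0.8)^2, tolerance = 1e-12)
  # early clone treated day 1 then lost: weight stays 1
  expect_true(all(wt$w[wt$clone_id == "lt3.early"] == 1))
})

test_that("boundary hazards trigger a positivity error", {
  el <- derive_outcomes(make_registry(make_subject("a", intervention_day = 8L)))
  cl <- make_clones(el, default_strategies())
  cd <- expand_person_days(cl)
  expect_error(
    compute_weights(cd, cl, el, constant_initiation_model(1 - 1e-12)),
    "positivity")
})

test_that("weights undo the artificial censoring in expectation", {
  # with no events or deaths, the weighted count of uncensored clones at the
  # end of each grace window equals the number of clones in that arm
  p <- flat_params(3000, seed = 25, init_h = 0.25, ext_intercept = -40)
  reg <- derive_outcomes(simulate_registry(p))
  el <- apply_eligibility(reg)$eligible
  cl <- make_clones(el, default_strategies())
  cd <- expand_person_days(cl)
  m <- fit_initiation_model(el)
  wt <- compute_weights(cd, cl, el, m, truncation = 1)
  cd$w <- wt$w
  for (arm in c("early", "late")) {
    end_day <- if (arm == "early") 4L else 14L
    mass <- sum(cd$w[cd$strategy == arm & cd$day == end_day &
                       cd$artificial_censor == 0])
    expect_equal(mass, nrow(el), tolerance = 0.03)
  }
})

test_that("stabilised and unstabilised weights give identical saturated curves", {
  reg <- simulate_registry(sim_preset("default", n_subjects = 600, seed = 26))
  f_w <- ccw_emulate(reg, time_spec = "saturated", truncation = 1,
                     weight_col = "w")
  f_sw <- ccw_emulate(reg, time_spec = "saturated", truncation = 1,
                      weight_col = "sw")
  expect_equal(f_sw$curves$cum_inc, f_w$curves$cum_inc, tolerance = 1e-12)
  # stabilised weights have bounded mean
  expect_lt(mean(f_w$weights$sw), 2)
})
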
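eligible3 <- function() {
  derive_outcomes(make_registry(
    make_subject("a", intervention_day = 3L),
    make_subject("b", intervention_day = 8L),
    make_subject("c")
  ))
}

test_that("each subject contributes one clone per compatible strategy", {
  cl <- make_clones(eligible3(), default_strategies())
  expect_equal(nrow(cl), 6L)
  expect_equal(sort(unique(cl$strategy)), c("early", "late"))
  expect_error(make_clones(eligible3(),
                           dplyr::bind_rows(strategy("x", 0, 4),
                                            strategy("x", 5, 14))),
               "duplicate")
})

test_that("age-axis windows already passed at referral are excluded with a log", {
  reg <- derive_outcomes(make_registry(
    make_subject("young", age_at_referral_days = 5L, intervention_day = 12L),
    make_subject("old", age_at_referral_days = 40L, intervention_day = 2L)
  ))
  cl <- make_clones(reg, age_axis_strategies(max_age_at_referral = NA))
  expect_equal(sort(unique(cl$subject_id)), "young")
  excl <- attr(cl, "excluded")
  expect_equal(sort(unique(excl$subject_id)), "old")
  # and the age cap restricts the population
  cl2 <- make_clones(reg, age_axis_strategies())  # cap 13 days
  expect_equal(sort(unique(cl2$subject_id)), "young")
})

test_that("deviation days follow the window semantics", {
  el <- eligible3()
  cl <- make_clones(el, default_strategies())
  dev <- function(id, st) cl$deviation_day[cl$subject_id == id & cl$strategy == st]
  # intervention day 3: adherent early, deviates from late on day 3
  expect_true(is.na(dev("a", "early")))
  expect_equal(dev("a", "late"), 3L)
  # intervention day 8: deviates from early at the day-4 deadline
  expect_equal(dev("b", "early"), 4L)
  expect_true(is.na(dev("b", "late")))
  # never treated: deadline deviations on days 4 and 14
  expect_equal(dev("c", "early"), 4L)
  expect_equal(dev("c", "late"), 14L)
})

test_that("early extubation without intervention is adherent to both arms", {
  el <- derive_outcomes(make_registry(
    make_subject("a", extubation_episodes = "2:0")))
  cl <- make_clones(el, default_strategies())
  expect_true(all(is.na(cl$deviation_day)))
  expect_equal(adherence_flow(cl)$pattern, "both")
})

test_that("death inside the grace period pre-empts deviation", {
  el <- derive_outcomes(make_registry(make_subject("a", death_day = 2L)))
  cl <- make_clones(el, default_strategies())
  expect_true(all(is.na(cl$deviation_day)))
  cd <- expand_person_days(cl)
  # dead clones persist as non-events through the horizon (total effect)
  expect_equal(nrow(cd), 2L * 46L)
  expect_true(all(cd$event == 0L))
  expect_true(all(cd$dead_by_t[cd$day >= 2]))
})

test_that("person-day rows match the stated counting examples", {
  el <- derive_outcomes(make_registry(
    make_subject("ev7", intervention_day = 1L, extubation_episodes = "7:0"),
    make_subject("dev4", intervention_day = 8L)
  ))
  cd <- expand_person_days(make_clones(el, default_strategies()))
  ev7_early <- cd[cd$clone_id == "ev7.early", ]
  expect_equal(nrow(ev7_early), 8L)
  expect_equal(ev7_early$event, c(rep(0L, 7), 1L))
  dev4_early <- cd[cd$clone_id == "dev4.early", ]
  expect_equal(nrow(dev4_early), 5L)
  expect_equal(dev4_early$artificial_censor, c(rep(0L, 4), 1L))
})

test_that("no clone has rows after its censoring day and events are unique", {
  reg <- derive_outcomes(random_registry(20, seed = 77))
  cl <- make_clones(reg, default_strategies())
  cd <- expand_person_days(cl)
  per <- dplyr::summarise(
    dplyr::group_by(cd, .data$clone_id),
    n_event = sum(.data$event), n_cens = sum(.data$artificial_censor),
    last = max(.data$day), .groups = "drop")
  expect_true(all(per$n_event <= 1))
  expect_true(all(per$n_cens <= 1))
  cens_day <- cd$day[cd$artificial_censor == 1]
  names(cens_day) <- cd$clone_id[cd$artificial_censor == 1]
  if (length(cens_day) > 0) {
    expect_equal(per$last[match(names(cens_day), per$clone_id)],
                 unname(cens_day))
  }
})

test_that("early and late clones share identical rows before the strategies diverge", {
  # strategies are compatible with identical data until an intervention or
  # the early deadline; rows before that day must agree column-for-column
  reg <- derive_outcomes(random_registry(15, seed = 99))
  cl <- make_clones(reg, default_strategies())
  cd <- expand_person_days(cl)
  for (sid in unique(cl$subject_id)) {
    diverge <- min(c(4L, cl$intervention_day[cl$subject_id == sid]), na.rm = TRUE)
    a <- cd[cd$subject_id == sid & cd$strategy == "early" & cd$day < diverge, ]
    b <- cd[cd$subject_id == sid & cd$strategy == "late" & cd$day < diverge, ]
    cols <- c("day", "treated_by_t", "at_risk", "event", "dead_by_t",
              "artificial_censor")
    expect_equal(as.data.frame(a[cols]), as.data.frame(b[cols]))
  }
})

test_that("censoring at death truncates rows at the day before death", {
  el <- derive_outcomes(make_registry(
    make_subject("a", intervention_day = 2L, death_day = 10L)))
  cl <- make_clones(el, default_strategies())
  cd <- expand_person_days(cl, competing = "censor_death")
  expect_equal(max(cd$day[cd$clone_id == "a.early"]), 9L)
  cd0 <- expand_person_days(
    make_clones(derive_outcomes(make_registry(
      make_subject("b", intervention_day = 0L, death_day = 0L))),
      default_strategies()),
    competing = "censor_death")
  expect_false("b.early" %in% cd0$clone_id)
})
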
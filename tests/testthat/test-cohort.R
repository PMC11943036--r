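test_that("registry round-trips through CSV unchanged", {
  reg <- make_registry(
    make_subject("a", intervention_day = 2L,
                 extubation_episodes = "10:1;20:0", death_day = NA),
    make_subject("b", intervention_day = NA, death_day = 30L),
    make_subject("c", intervention_day = 7L, ltfu_day = 12L,
                 gestational_age_weeks = 28.5, birth_weight_g = 1100)
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write_registry(reg, path)
  back <- read_registry(path)
  expect_equal(as.data.frame(back[names(reg)]), as.data.frame(reg))
})

test_that("an empty registry file with a header reads as an empty collection", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_registry(make_subject()[0, ], path)
  expect_equal(nrow(read_registry(path)), 0L)
})

test_that("schema violations are reported by name and row", {
  path <- withr::local_tempfile(fileext = ".csv")
  reg <- make_subject("a")
  write_registry(reg, path)
  txt <- readLines(path)
  writeLines(gsub("death_day", "day_of_death", txt), path)
  expect_error(read_registry(path), "death_day")

  reg2 <- make_subject("a")
  reg2$intervention_day <- 2.5
  path2 <- withr::local_tempfile(fileext = ".csv")
  suppressWarnings(readr::write_csv(reg2, path2))
  expect_error(read_registry(path2), "intervention_day")
})

test_that("event-day invariants are enforced", {
  bad <- make_subject("a", extubation_episodes = "20:0", death_day = 10L)
  expect_error(validate_registry(bad), "death")
  bad2 <- make_subject("a", extubation_episodes = "5:0;5:1")
  expect_error(validate_registry(bad2), "increasing")
  bad3 <- make_registry(make_subject("a"), make_subject("a"))
  expect_error(validate_registry(bad3), "duplicate")
})

test_that("eligibility follows the trial criteria", {
  # disjunctive prematurity inclusion: GA under 30 suffices despite BW 1600
  ok <- apply_eligibility(make_subject("a", gestational_age_weeks = 29,
                                       birth_weight_g = 1600))
  expect_equal(ok$n_eligible, 1L)
  # tracheostomy excludes even an otherwise-included infant
  tr <- apply_eligibility(make_subject("a", gestational_age_weeks = 31,
                                       birth_weight_g = 1400,
                                       tracheostomy = TRUE))
  expect_equal(tr$n_eligible, 0L)
  expect_equal(tr$tally$n_excluded[tr$tally$criterion == "tracheostomy"], 1L)
  # conjunction: not ventilated at referral fails regardless
  nv <- apply_eligibility(make_subject("a", ventilated_at_referral = FALSE))
  expect_equal(nv$n_eligible, 0L)
  # contraindication substitutes for prior pharmacotherapy
  ci <- apply_eligibility(make_subject("a", prior_pharmacotherapy = FALSE,
                                       pharmacotherapy_contraindicated = TRUE))
  expect_equal(ci$n_eligible, 1L)
  # a missing flag never qualifies
  na_flag <- apply_eligibility(make_subject("a", ventilated_at_referral = NA))
  expect_equal(na_flag$n_eligible, 0L)
})

test_that("eligibility is monotone in clearing exclusion flags", {
  set.seed(31)
  flags <- c("complex_chd", "bidirectional_or_r2l_flow", "major_anomaly",
             "tracheostomy")
  for (i in 1:20) {
    sub <- make_subject("a",
                        complex_chd = runif(1) < 0.5,
                        bidirectional_or_r2l_flow = runif(1) < 0.5,
                        major_anomaly = runif(1) < 0.5,
                        tracheostomy = runif(1) < 0.5)
    before <- apply_eligibility(sub)$n_eligible
    cleared <- sub
    cleared[flags] <- FALSE
    after <- apply_eligibility(cleared)$n_eligible
    expect_gte(after, before)
  }
})

test_that("the outcome day is the first unreversed extubation", {
  expect_equal(derive_outcome_day(tibble::tibble(
    extubation_day = c(10L, 20L), reintubated_within_7d = c(TRUE, FALSE))),
    20L)
  expect_true(is.na(derive_outcome_day(tibble::tibble(
    extubation_day = integer(0), reintubated_within_7d = logical(0)))))
  # confirmation window truncated by the data end still counts
  expect_equal(derive_outcome_day(tibble::tibble(
    extubation_day = 44L, reintubated_within_7d = FALSE), horizon = 45L),
    44L)
  # an episode on/after death or loss to follow-up does not count
  expect_true(is.na(derive_outcome_day(tibble::tibble(
    extubation_day = 20L, reintubated_within_7d = FALSE), death_day = 20L)))
})

test_that("derive_outcomes is vectorised and ignores episodes after success", {
  reg <- make_registry(
    make_subject("a", extubation_episodes = "10:1;20:0"),
    make_subject("b"),
    make_subject("c", extubation_episodes = "5:0;9:0")
  )
  out <- derive_outcomes(reg)
  expect_equal(out$outcome_day, c(20L, NA, 5L))
  # removing an episode after the returned day changes nothing
  reg$extubation_episodes[3] <- "5:0"
  expect_equal(derive_outcomes(reg)$outcome_day[3], 5L)
})
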
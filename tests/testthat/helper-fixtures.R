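# Fixture builders and independent oracles shared across the test files.

# One registry row with sensible defaults; override any field.
make_subject <- function(subject_id = "s1",
                         gestational_age_weeks = 25,
                         birth_weight_g = 700,
                         age_at_referral_days = 10L,
                         sex = "female",
                         referral_year = 2020L,
                         prior_pharmacotherapy = TRUE,
                         pharmacotherapy_contraindicated = FALSE,
                         ventilated_at_referral = TRUE,
                         complex_chd = FALSE,
                         bidirectional_or_r2l_flow = FALSE,
                         major_anomaly = FALSE,
                         tracheostomy = FALSE,
                         intervention_day = NA_integer_,
                         extubation_episodes = "",
                         death_day = NA_integer_,
                         ltfu_day = NA_integer_) {
  tibble::tibble(
    subject_id = subject_id,
    gestational_age_weeks = gestational_age_weeks,
    birth_weight_g = birth_weight_g,
    age_at_referral_days = as.integer(age_at_referral_days),
    sex = sex, referral_year = as.integer(referral_year),
    prior_pharmacotherapy = prior_pharmacotherapy,
    pharmacotherapy_contraindicated = pharmacotherapy_contraindicated,
    ventilated_at_referral = ventilated_at_referral,
    complex_chd = complex_chd,
    bidirectional_or_r2l_flow = bidirectional_or_r2l_flow,
    major_anomaly = major_anomaly,
    tracheostomy = tracheostomy,
    intervention_day = as.integer(intervention_day),
    extubation_episodes = extubation_episodes,
    death_day = as.integer(death_day),
    ltfu_day = as.integer(ltfu_day)
  )
}

make_registry <- function(...) dplyr::bind_rows(...)

# Simulation parameters with a constant, covariate-free initiation hazard
# and tunable event processes; used for closed-form checks.
flat_params <- function(n, seed, init_h = 0.2, ext_intercept = -40,
                        treated = 0, tst = 0, death = 0, ltfu = 0,
                        reint = 0) {
  sim_params(
    n_subjects = n, seed = seed,
    initiation_coefs = c(intercept = stats::qlogis(init_h), day = 0,
                         bw_z = 0, ga_z = 0, age_z = 0, sex_female = 0,
                         year_c = 0, prior_pharmacotherapy = 0),
    extubation_coefs = c(intercept = ext_intercept, treated = treated,
                         time_since_treatment = tst, bw_z = 0, ga_z = 0),
    death_hazard = c(untreated = death, treated = death),
    ltfu_hazard = ltfu,
    reintubation_prob = reint
  )
}

# ---------------------------------------------------------------------------
# Independent brute-force oracle for the clone-censor bookkeeping: walks one
# subject's follow-up day by day for one strategy window on the referral
# clock, applying the protocol rules in their stated precedence. Returns the
# rows the clone should contribute and its terminal classification.
brute_clone <- function(sub, ref_start, ref_end, horizon = 45L,
                        competing = "total") {
  int <- sub$intervention_day
  out <- sub$outcome_day
  death <- sub$death_day
  ltfu <- sub$ltfu_day
  n_rows <- 0L
  terminal <- "admin"
  terminal_day <- NA_integer_
  dead <- FALSE
  for (t in 0:horizon) {
    if (competing == "censor_death" && !is.na(death) && t >= death) {
      terminal <- "admin"
      terminal_day <- t - 1L
      break
    }
    n_rows <- n_rows + 1L
    # precedence within the day: event, deviation, administrative censoring
    if (!is.na(out) && out == t) {
      terminal <- "event"
      terminal_day <- t
      break
    }
    if (!dead) {
      premature <- !is.na(int) && int < ref_start && int == t
      missed <- (is.na(int) || int > ref_end) && t == ref_end
      if ((premature || missed) && !(!is.na(death) && death <= t)) {
        terminal <- "deviation"
        terminal_day <- t
        break
      }
    }
    if (!is.na(ltfu) && ltfu == t) {
      terminal <- "admin"
      terminal_day <- t
      break
    }
    if (!is.na(death) && death == t) dead <- TRUE
    if (t == horizon) {
      terminal <- "admin"
      terminal_day <- t
    }
  }
  list(n_rows = n_rows, terminal = terminal, terminal_day = terminal_day)
}

# Random small registries exercising the censoring edge cases: events on
# window boundaries, deaths inside the grace period, loss to follow-up,
# untreated subjects, and interventions before/inside/after each window.
random_registry <- function(n, seed, horizon = 45L) {
  set.seed(seed)
  rows <- lapply(seq_len(n), function(i) {
    death <- if (runif(1) < 0.25) sample(0:horizon, 1) else NA_integer_
    last_alive <- if (is.na(death)) horizon else death - 1L
    int <- NA_integer_
    if (runif(1) < 0.75 && last_alive >= 0L) {
      int <- sample(0:min(18L, last_alive), 1)
    }
    ltfu <- NA_integer_
    if (!is.na(int) && runif(1) < 0.3) {
      lo <- int + 1L
      hi <- if (is.na(death)) horizon else death - 1L
      if (lo <= hi) ltfu <- sample(lo:hi, 1)
    }
    last_obs <- min(last_alive, if (is.na(ltfu)) horizon else ltfu)
    eps <- ""
    if (runif(1) < 0.7 && last_obs >= 0L) {
      k <- sample(1:3, 1)
      days <- sort(sample(0:min(horizon, last_obs), min(k, last_obs + 1L)))
      reint <- runif(length(days)) < 0.5
      if (length(days) > 0) {
        eps <- paste(sprintf("%d:%d", days, as.integer(reint)), collapse = ";")
      }
    }
    make_subject(subject_id = sprintf("r%03d", i), intervention_day = int,
                 extubation_episodes = eps, death_day = death,
                 ltfu_day = ltfu)
  })
  dplyr::bind_rows(rows)
}
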
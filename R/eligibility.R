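#' Screen a registry for trial eligibility
#'
#' Applies the emulated trial's eligibility criteria: born before 30 weeks
#' of gestation or under 1500 g; mechanically ventilated at referral; at
#' least one prior course of PDA pharmacotherapy unless contraindicated; and
#' none of the exclusions (complex congenital cardiac disease, bidirectional
#' or right-to-left ductal flow, major congenital anomaly, tracheostomy).
#' A missing flag never qualifies a subject: it is treated as failing that
#' criterion and the subject is logged under it.
#'
#' Exclusions are tallied in a fixed order, each subject attributed to the
#' first criterion it fails, mirroring a recruitment flowchart.
#'
#' @param subjects Registry tibble ([registry-schema]).
#' @return A list of class `ccw_eligibility`:
#'   * `eligible` — the eligible subjects (tibble),
#'   * `tally` — tibble `(criterion, n_excluded)` in screening order,
#'   * `n_screened`, `n_eligible` — counts.
#' @export
#' @examples
#' reg <- simulate_registry(sim_params(n_subjects = 200, seed = 3))
#' el <- apply_eligibility(reg)
#' el$tally
apply_eligibility <- function(subjects) {
  validate_registry(subjects)
  isTRUEv <- function(x) !is.na(x) & x
  crit <- list(
    not_preterm_or_low_birth_weight =
      !(isTRUEv(subjects$gestational_age_weeks < 30) |
          isTRUEv(subjects$birth_weight_g < 1500)),
    not_ventilated_at_referral = !isTRUEv(subjects$ventilated_at_referral),
    no_prior_pharmacotherapy_or_contraindication =
      !(isTRUEv(subjects$prior_pharmacotherapy) |
          isTRUEv(subjects$pharmacotherapy_contraindicated)),
    complex_congenital_cardiac_disease = isTRUEv(subjects$complex_chd),
    bidirectional_or_r2l_pda_flow = isTRUEv(subjects$bidirectional_or_r2l_flow),
    major_congenital_anomaly = isTRUEv(subjects$major_anomaly),
    tracheostomy = isTRUEv(subjects$tracheostomy)
  )
  # first failing criterion wins
  fail_at <- rep(NA_integer_, nrow(subjects))
  for (i in rev(seq_along(crit))) fail_at[crit[[i]]] <- i
  tally <- tibble::tibble(
    criterion = names(crit),
    n_excluded = vapply(seq_along(crit),
                        function(i) sum(fail_at == i, na.rm = TRUE),
                        integer(1))
  )
  structure(
    list(eligible = subjects[is.na(fail_at), , drop = FALSE],
         tally = tally,
         n_screened = nrow(subjects),
         n_eligible = sum(is.na(fail_at))),
    class = "ccw_eligibility"
  )
}

#' @export
print.ccw_eligibility <- function(x, ...) {
  cat(sprintf("<ccw_eligibility> %d screened, %d eligible\n",
              x$n_screened, x$n_eligible))
  excl <- x$tally[x$tally$n_excluded > 0, ]
  if (nrow(excl) > 0) {
    for (i in seq_len(nrow(excl))) {
      cat(sprintf("  excluded %3d  %s\n", excl$n_excluded[i], excl$criterion[i]))
    }
  }
  invisible(x)
}

#' @export
tidy.ccw_eligibility <- function(x, ...) x$tally

#' @export
glance.ccw_eligibility <- function(x, ...) {
  tibble::tibble(n_screened = x$n_screened, n_eligible = x$n_eligible,
                 n_excluded = x$n_screened - x$n_eligible)
}
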
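#' Present-value discount factor
#'
#' @param rate Annual discount rate as a fraction (0.05 = 5%/year).
#' @param t Cycle index (integer >= 0); vectorised.
#' @return `(1 + rate)^(-t)`.
#' @examples
#' discount_factor(0.05, 0:2)  # 1, 0.952381, 0.907029
#' @export
discount_factor <- function(rate, t) {
  stopifnot(is.numeric(rate), length(rate) == 1L, rate >= 0)
  if (any(t < 0) || any(t != round(t))) {
    stop("t must be a nonnegative integer cycle index", call. = FALSE)
  }
  (1 + rate)^(-t)
}

#' Run the annual-cycle cohort model for one strategy
#'
#' Evolves the expected state occupancy (well / breast cancer / ovarian
#' cancer) of each arm over `n_cycles` one-year cycles.  From the well state,
#' the annual breast and ovarian transition probabilities compete; the joint
#' same-cycle mass `p_b * p_o` is assigned to the breast state by default
#' (the higher-incidence site; the alternative tie-break is provided to show
#' the choice is immaterial at realistic risks).  Cancer states are
#' absorbing, and there is no death state: effectiveness is cancer cases,
#' not life-years.
#'
#' Accrual conventions (no half-cycle correction):
#' * one-off arm costs accrue at cycle 0, undiscounted;
#' * per-cycle costs accrue for well-state occupants at the start of each
#'   cycle `t` in `0..n_cycles-1`, discounted by `(1+rate)^-t`;
#' * new cancer cases arising during cycle `t` are counted at `t+1`,
#'   discounted by `(1+rate)^-(t+1)`.
#'
#' @param strategy A `cea_strategy` object.
#' @param n_cycles Number of annual cycles (40 at the default age horizon).
#' @param rate Annual discount rate applied to both costs and cases.
#' @param tie_break Which cancer state receives the joint same-cycle
#'   transition mass: `"breast"` (default) or `"ovarian"`.
#' @return A `cea_trace` object: occupancy array `[arm, cycle 0..n, state]`,
#'   per-cycle discounted cost and case accruals (cohort-weighted), their
#'   cumulative sums, discounted well-state person-years, and the arm table.
#' @export
run_cohort <- function(strategy, n_cycles = 40L, rate = 0.05,
                       tie_break = c("breast", "ovarian")) {
  stopifnot(inherits(strategy, "cea_strategy"), n_cycles >= 1L)
  tie_break <- match.arg(tie_break)
  arms <- strategy$arms
  n_arms <- nrow(arms)
  states <- c("well", "breast_cancer", "ovarian_cancer")

  occ <- array(0, dim = c(n_arms, n_cycles + 1L, 3L),
               dimnames = list(arms$label, NULL, states))
  occ[, 1L, "well"] <- 1

  pb <- arms$p_breast_annual
  po <- arms$p_ovarian_annual
  if (tie_break == "breast") {
    to_breast <- pb
    to_ovarian <- po * (1 - pb)
  } else {
    to_breast <- pb * (1 - po)
    to_ovarian <- po
  }
  stay_well <- (1 - pb) * (1 - po)
  hazard <- to_breast + to_ovarian   # total annual exit probability from well
  w <- arms$weight

  disc_cost <- numeric(n_cycles)
  disc_cases <- numeric(n_cycles)
  disc_well_years <- 0
  for (t in seq_len(n_cycles)) {
    well <- occ[, t, "well"]
    df_start <- discount_factor(rate, t - 1L)  # start of cycle t (index t-1)
    disc_cost[t] <- sum(w * well * arms$percycle_cost) * df_start
    disc_well_years <- disc_well_years + sum(w * well) * df_start
    new_cases <- well * hazard
    disc_cases[t] <- sum(w * new_cases) * discount_factor(rate, t)

    occ[, t + 1L, "well"] <- well * stay_well
    occ[, t + 1L, "breast_cancer"] <- occ[, t, "breast_cancer"] + well * to_breast
    occ[, t + 1L, "ovarian_cancer"] <- occ[, t, "ovarian_cancer"] + well * to_ovarian

    totals <- rowSums(occ[, t + 1L, , drop = FALSE])
    if (any(abs(totals - 1) > 1e-12) || any(occ[, t + 1L, ] < 0)) {
      stop("internal consistency error: occupancy not conserved at cycle ", t,
           call. = FALSE)
    }
  }

  oneoff <- sum(w * arms$oneoff_cost)
  trace <- list(
    strategy = strategy$name,
    arms = arms,
    n_cycles = as.integer(n_cycles),
    rate = rate,
    occupancy = occ,
    oneoff_cost = oneoff,
    disc_cost_by_cycle = disc_cost,
    disc_cases_by_cycle = disc_cases,
    cum_disc_cost = oneoff + cumsum(disc_cost),
    cum_disc_cases = cumsum(disc_cases),
    disc_well_person_years = disc_well_years
  )
  class(trace) <- "cea_trace"
  trace
}

#' Summarise a cohort trace into a strategy outcome
#'
#' The expected cost is the cumulative discounted cost per relative; the
#' expected case count is the cumulative discounted cancer cases per
#' relative.  Two effectiveness conventions are offered because published
#' cost-per-case-prevented analyses report effectiveness on unit-unstated
#' scales: `"per100"` (default), the discounted cancer-free index
#' `(1 - expected_cases) * 100`, and `"person_years"`, discounted well-state
#' person-years accrued at cycle starts (same timing as per-cycle costs,
#' maximum 18.02 over 40 undiscounted-free years at 5%).
#'
#' @param trace A `cea_trace` from [run_cohort()].
#' @param convention Effectiveness scale, `"per100"` or `"person_years"`.
#' @return A `cea_outcome` list: `strategy`, `expected_cost`,
#'   `expected_cases`, `effectiveness`, `convention`.
#' @export
strategy_outcome <- function(trace, convention = c("per100", "person_years")) {
  stopifnot(inherits(trace, "cea_trace"))
  convention <- match.arg(convention)
  nc <- trace$n_cycles
  expected_cost <- trace$cum_disc_cost[nc]
  expected_cases <- trace$cum_disc_cases[nc]
  effectiveness <- switch(convention,
    per100 = (1 - expected_cases) * 100,
    person_years = trace$disc_well_person_years
  )
  structure(list(strategy = trace$strategy,
                 expected_cost = expected_cost,
                 expected_cases = expected_cases,
                 effectiveness = effectiveness,
                 convention = convention),
            class = "cea_outcome")
}

#' Export a cohort trace as CSV
#'
#' One row per (arm, cycle, state) with the occupancy fraction, plus the
#' cohort-level per-cycle discounted cost and case accruals repeated on the
#' `well` rows of the first arm for convenience.
#'
#' @param trace A `cea_trace` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  occ <- trace$occupancy
  dn <- dimnames(occ)
  long <- expand.grid(arm = dn[[1]], cycle = 0:trace$n_cycles,
                      state = dn[[3]], stringsAsFactors = FALSE)
  long$occupancy <- as.vector(occ)
  long$disc_cost <- NA_real_
  long$disc_cases <- NA_real_
  sel <- long$arm == dn[[1]][1] & long$state == "well" & long$cycle >= 1
  long$disc_cost[sel] <- trace$disc_cost_by_cycle
  long$disc_cases[sel] <- trace$disc_cases_by_cycle
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' @export
print.cea_trace <- function(x, ...) {
  cat(sprintf("<cea_trace> %s: %d arms, %d cycles, discount rate %.1f%%\n",
              x$strategy, nrow(x$arms), x$n_cycles, 100 * x$rate))
  cat(sprintf("  expected discounted cost:  R$%.2f\n", x$cum_disc_cost[x$n_cycles]))
  cat(sprintf("  expected discounted cases: %.4f\n", x$cum_disc_cases[x$n_cycles]))
  cat(sprintf("  discounted well person-years: %.4f\n", x$disc_well_person_years))
  invisible(x)
}

#' @export
print.cea_outcome <- function(x, ...) {
  cat(sprintf("<cea_outcome> %s\n", x$strategy))
  cat(sprintf("  expected cost:  R$%.2f\n", x$expected_cost))
  cat(sprintf("  expected cases: %.4f (discounted)\n", x$expected_cases))
  cat(sprintf("  effectiveness:  %.4f (%s)\n", x$effectiveness, x$convention))
  invisible(x)
}
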
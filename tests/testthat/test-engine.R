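test_that("discount factors follow (1+r)^-t", {
  expect_identical(discount_factor(0.05, 0L), 1)
  expect_equal(discount_factor(0.05, 1L), 1 / 1.05, tolerance = 1e-15)
  expect_identical(discount_factor(0, 17L), 1)
  expect_equal(discount_factor(0.05, 0:2), c(1, 1 / 1.05, 1 / 1.05^2))
  expect_error(discount_factor(0.05, -1L), "nonnegative")
  expect_error(discount_factor(0.05, 1.5))
})

test_that("a risk-free cohort accrues the annuity-due of its per-cycle cost", {
  # independent oracle: direct summation of the 40-term discounted annuity
  annuity <- sum(1.05^-(0:39))
  expect_equal(annuity, 18.0170406716942, tolerance = 1e-12)

  strat <- toy_strategy(pb = 0, po = 0, oneoff = 100, percycle = 10)
  trace <- run_cohort(strat, 40L, 0.05)
  out <- strategy_outcome(trace)
  expect_equal(out$expected_cases, 0)
  expect_equal(out$expected_cost, 100 + 10 * annuity, tolerance = 1e-12)
  expect_equal(out$effectiveness, 100)  # per-100 boundary
  expect_equal(strategy_outcome(trace, "person_years")$effectiveness, annuity,
               tolerance = 1e-12)
})

test_that("a certain transition absorbs the whole cohort in one cycle", {
  strat <- toy_strategy(pb = 1, po = 0)
  trace <- run_cohort(strat, 1L, 0)
  expect_equal(trace$occupancy[1, 2, "breast_cancer"], 1)
  expect_equal(trace$occupancy[1, 2, "well"], 0)
  expect_equal(strategy_outcome(trace)$expected_cases, 1)
})

test_that("undiscounted cohort case totals equal the closed-form absorption probability", {
  params <- load_parameters()
  for (build in list(build_testing_strategy, build_usual_care_strategy)) {
    strat <- build(params)
    arms <- as.data.frame(strat)
    for (nc in c(1L, 7L, 40L)) {
      trace <- run_cohort(strat, nc, rate = 0)
      pb <- arms$p_breast_annual; po <- arms$p_ovarian_annual
      analytic <- sum(arms$weight * (1 - (1 - pb - po + pb * po)^nc))
      expect_equal(trace$cum_disc_cases[nc], analytic, tolerance = 1e-12)
    }
  }
})

test_that("occupancy is conserved and cumulative accruals are nondecreasing", {
  params <- load_parameters()
  set.seed(11)
  strategies <- c(
    list(build_testing_strategy(params), build_usual_care_strategy(params)),
    lapply(1:5, function(i) {
      k <- sample(1:4, 1)
      w <- stats::rgamma(k, 1); w <- w / sum(w)
      toy_strategy(pb = stats::runif(k, 0, 0.2), po = stats::runif(k, 0, 0.2),
                   weight = w, oneoff = stats::runif(k, 0, 100),
                   percycle = stats::runif(k, 0, 50))
    })
  )
  for (strat in strategies) {
    trace <- run_cohort(strat, 40L, 0.05)
    sums <- apply(trace$occupancy, c(1, 2), sum)
    expect_true(all(abs(sums - 1) <= 1e-12))
    expect_true(all(trace$occupancy >= 0))
    expect_true(all(diff(trace$cum_disc_cost) >= 0))
    expect_true(all(diff(trace$cum_disc_cases) >= 0))
  }
})

test_that("expected cost scales linearly in all unit costs", {
  strat <- toy_strategy(pb = c(0.02, 0.01), po = c(0.01, 0.002),
                        weight = c(0.3, 0.7), oneoff = c(100, 20),
                        percycle = c(30, 5))
  k <- 3.7
  scaled <- toy_strategy(pb = c(0.02, 0.01), po = c(0.01, 0.002),
                         weight = c(0.3, 0.7), oneoff = k * c(100, 20),
                         percycle = k * c(30, 5))
  c1 <- strategy_outcome(run_cohort(strat, 40L, 0.05))$expected_cost
  c2 <- strategy_outcome(run_cohort(scaled, 40L, 0.05))$expected_cost
  expect_equal(c2, k * c1, tolerance = 1e-12)
})

test_that("the same-cycle tie-break convention is immaterial at model risks", {
  params <- load_parameters()
  for (build in list(build_testing_strategy, build_usual_care_strategy)) {
    strat <- build(params)
    a <- run_cohort(strat, 40L, 0.05, tie_break = "breast")
    b <- run_cohort(strat, 40L, 0.05, tie_break = "ovarian")
    expect_lt(abs(a$cum_disc_cases[40] - b$cum_disc_cases[40]), 1e-3)
    expect_lt(abs(a$cum_disc_cost[40] - b$cum_disc_cost[40]) /
                a$cum_disc_cost[40], 1e-3)
    expect_lt(abs(a$disc_well_person_years - b$disc_well_person_years), 1e-3)
  }
})

test_that("the intervention is costlier and more effective than usual care at defaults", {
  params <- load_parameters()
  nc <- n_cycles(params)
  rate <- params$structure$discount_rate
  o1 <- strategy_outcome(run_cohort(build_testing_strategy(params), nc, rate))
  o0 <- strategy_outcome(run_cohort(build_usual_care_strategy(params), nc, rate))
  expect_gt(o1$expected_cost, o0$expected_cost)
  expect_gt(o1$effectiveness, o0$effectiveness)
  expect_lt(o1$expected_cases, o0$expected_cases)
})

test_that("trace export writes one row per arm-cycle-state", {
  strat <- toy_strategy(pb = c(0.1, 0.2), po = c(0.05, 0.1))
  trace <- run_cohort(strat, 5L, 0.05)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace_csv(trace, path)
  tab <- utils::read.csv(path)
  expect_equal(nrow(tab), 2 * 6 * 3)
  expect_equal(sum(tab$disc_cases, na.rm = TRUE), trace$cum_disc_cases[5],
               tolerance = 1e-12)
})
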
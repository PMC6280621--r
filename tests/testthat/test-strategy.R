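test_that("carrier proportions follow the prevalence split and transmission", {
  p <- carrier_proportions(0.17, 0.02, 0.5)
  expect_equal(unname(p), c(0.17 / 0.19 * 0.5, 0.02 / 0.19 * 0.5,
                            1 - 0.5), tolerance = 1e-12)
  expect_equal(sum(p), 1)
  expect_equal(unname(round(100 * p)), c(45, 5, 50))

  expect_equal(unname(carrier_proportions(0.19, 0, 0.5)), c(0.5, 0, 0.5))
  expect_equal(unname(carrier_proportions(0.17, 0.02, 1.0)),
               c(0.17 / 0.19, 0.02 / 0.19, 0), tolerance = 1e-12)
  expect_error(carrier_proportions(0, 0, 0.5), "positive")
})

test_that("testing strategy enumerates the adherence arms with the published weights", {
  params <- load_parameters()
  strat <- build_testing_strategy(params)
  arms <- as.data.frame(strat)

  expect_equal(nrow(arms), 9L)
  expect_equal(sum(arms$weight), 1, tolerance = 1e-12)
  expect_equal(arms$weight[arms$label == "no_mutation"], 0.50)
  expect_equal(sum(arms$weight[grepl("^brca1", arms$label)]), 0.45,
               tolerance = 1e-12)
  expect_equal(sum(arms$weight[grepl("^brca2", arms$label)]), 0.05,
               tolerance = 1e-12)
  # joint adherence under independence
  expect_equal(arms$weight[arms$label == "brca1_both"], 0.45 * 0.18 * 0.57)
  expect_equal(arms$weight[arms$label == "brca2_no_surgery"],
               0.05 * (1 - 0.18) * (1 - 0.57))

  # every relative is counselled and tested; surgery costs stack on top
  base <- 200 + 683.61
  expect_true(all(arms$oneoff_cost >= base))
  expect_equal(arms$oneoff_cost[arms$label == "no_mutation"], base)
  expect_equal(arms$oneoff_cost[arms$label == "brca1_both"],
               base + 3158.04 + 542.46)
  expect_equal(arms$oneoff_cost[arms$label == "brca1_rrso_only"], base + 542.46)
  expect_equal(arms$oneoff_cost[arms$label == "brca1_mx_only"], base + 3158.04)

  # breast screening only in carrier arms that refuse mastectomy
  refused_mx <- grepl("rrso_only|no_surgery", arms$label)
  expect_equal(arms$percycle_cost[refused_mx], rep(333.75, 4))
  expect_equal(arms$percycle_cost[!refused_mx], rep(0, 5))

  # risks are the converted post-surgery penetrances
  expect_equal(arms$p_breast_annual[arms$label == "brca1_both"],
               lifetime_to_annual(0.02, 40))
  expect_equal(arms$p_ovarian_annual[arms$label == "brca1_both"],
               lifetime_to_annual(0.08, 40))
  expect_equal(arms$p_breast_annual[arms$label == "no_mutation"],
               lifetime_to_annual(0.06, 40))
  expect_equal(arms$p_ovarian_annual[arms$label == "no_mutation"],
               lifetime_to_annual(0.006, 40))
})

test_that("full adherence collapses refusal arms to zero weight", {
  params <- load_parameters()
  params <- set_prob_point(params, "p_adhere_mastectomy", 1)
  params <- set_prob_point(params, "p_adhere_rrso", 1)
  params$probs$low[params$probs$name %in%
                     c("p_adhere_mastectomy", "p_adhere_rrso")] <- NA_real_
  params$probs$high[params$probs$name %in%
                      c("p_adhere_mastectomy", "p_adhere_rrso")] <- NA_real_
  arms <- as.data.frame(build_testing_strategy(params))
  nonzero <- arms$label[arms$weight > 0]
  expect_setequal(nonzero, c("brca1_both", "brca2_both", "no_mutation"))
})

test_that("usual care keeps the latent mixture, no intervention costs, expected screening everywhere", {
  params <- load_parameters()
  strat <- build_usual_care_strategy(params)
  arms <- as.data.frame(strat)

  expect_equal(nrow(arms), 3L)
  expect_equal(sum(arms$weight), 1, tolerance = 1e-12)
  expect_equal(arms$weight, c(0.45, 0.05, 0.50))
  expect_equal(arms$oneoff_cost, rep(0, 3))
  expect_equal(arms$percycle_cost, rep(0.24 * 333.75, 3))  # R$80.10
  expect_equal(arms$percycle_cost, rep(80.10, 3))

  expect_equal(arms$p_ovarian_annual[arms$label == "brca1_untested"],
               lifetime_to_annual(0.40, 40))
  expect_equal(arms$p_breast_annual[arms$label == "brca2_untested"],
               lifetime_to_annual(0.49, 40))
})

test_that("post-surgery annual risks never exceed unoperated risks", {
  params <- load_parameters()
  test_arms <- as.data.frame(build_testing_strategy(params))
  uc_arms <- as.data.frame(build_usual_care_strategy(params))
  for (gene in c("brca1", "brca2")) {
    base_b <- uc_arms$p_breast_annual[uc_arms$label == paste0(gene, "_untested")]
    base_o <- uc_arms$p_ovarian_annual[uc_arms$label == paste0(gene, "_untested")]
    sub <- test_arms[grepl(paste0("^", gene), test_arms$label), ]
    expect_true(all(sub$p_breast_annual <= base_b))
    expect_true(all(sub$p_ovarian_annual <= base_o))
  }
})

test_that("a costless, effect-free intervention is outcome-identical to usual care", {
  params <- neutral_parameters()
  nc <- n_cycles(params)
  rate <- params$structure$discount_rate
  t1 <- run_cohort(build_testing_strategy(params), nc, rate)
  t0 <- run_cohort(build_usual_care_strategy(params), nc, rate)
  for (conv in c("per100", "person_years")) {
    o1 <- strategy_outcome(t1, conv)
    o0 <- strategy_outcome(t0, conv)
    expect_equal(o1$expected_cost, o0$expected_cost, tolerance = 1e-12)
    expect_equal(o1$expected_cases, o0$expected_cases, tolerance = 1e-12)
    expect_equal(o1$effectiveness, o0$effectiveness, tolerance = 1e-12)
  }
})

test_that("strategy construction fails loudly on invalid parameters", {
  params <- load_parameters()
  params$costs$amount[params$costs$name == "mastectomy"] <- -5
  expect_error(build_testing_strategy(params), "mastectomy")
})
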
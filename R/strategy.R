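#' Mutation-carrier proportions among first-degree relatives
#'
#' Among first-degree relatives of ovarian-cancer patients whose tumour
#' carries a pathogenic germline variant, the probability of carrying the
#' family's mutation is the gene-specific share of the patient prevalence
#' times the autosomal-dominant transmission probability:
#' `p_gene = (prev_gene / (prev1 + prev2)) * transmission`.
#'
#' @param prev1,prev2 Prevalence of BRCA1 / BRCA2 mutations among the index
#'   patients (defaults 0.17 and 0.02).
#' @param transmission Transmission probability to a first-degree relative
#'   (0.5 for autosomal dominant inheritance).
#' @return Named numeric vector `c(brca1 =, brca2 =, none =)` summing to 1.
#' @examples
#' round(100 * carrier_proportions(0.17, 0.02, 0.5))  # 45 / 5 / 50
#' @export
carrier_proportions <- function(prev1, prev2, transmission) {
  stopifnot(prev1 >= 0, prev1 <= 1, prev2 >= 0, prev2 <= 1,
            prev1 + prev2 <= 1, transmission >= 0, transmission <= 1)
  if (prev1 + prev2 == 0) {
    stop("prev1 + prev2 must be positive: no mutation-positive families",
         call. = FALSE)
  }
  p1 <- prev1 / (prev1 + prev2) * transmission
  p2 <- prev2 / (prev1 + prev2) * transmission
  c(brca1 = p1, brca2 = p2, none = 1 - p1 - p2)
}

new_strategy <- function(name, arms) {
  w <- sum(arms$weight)
  if (abs(w - 1) > 1e-12) {
    stop("arm weights must sum to 1 (got ", format(w, digits = 15), ")",
         call. = FALSE)
  }
  if (any(arms$weight < 0) || any(arms$oneoff_cost < 0) ||
      any(arms$percycle_cost < 0)) {
    stop("arm weights and costs must be nonnegative", call. = FALSE)
  }
  structure(list(name = name, arms = arms), class = "cea_strategy")
}

#' Build the genetic-testing-plus-prophylaxis strategy
#'
#' Constructs the intervention strategy as a weighted decision tree feeding
#' a common Markov structure.  Every relative receives genetic counselling
#' and NGS+MLPA testing at entry.  Mutation carriers are offered bilateral
#' prophylactic mastectomy and risk-reducing salpingo-oophorectomy (RRSO);
#' uptake of the two surgeries is modelled as independent, giving four
#' adherence arms per gene.  Carriers who refuse mastectomy receive annual
#' breast MRI + mammography screening while cancer-free; ovarian screening
#' is never offered (no effective modality).  Test-negative relatives carry
#' population cancer risks and no further costs.  Cumulative penetrances are
#' converted to annual transition probabilities by [lifetime_to_annual()]
#' over the model horizon.
#'
#' @param params A `cea_parameters` object.
#' @return A `cea_strategy` object whose `arms` data frame has columns
#'   `label`, `weight`, `p_breast_annual`, `p_ovarian_annual`, `oneoff_cost`,
#'   `percycle_cost`.
#' @export
build_testing_strategy <- function(params) {
  violations <- validate_parameters(params)
  if (length(violations) > 0L) {
    stop("cannot build strategy from invalid parameters:\n  ",
         paste(violations, collapse = "\n  "), call. = FALSE)
  }
  nc <- n_cycles(params)
  p <- function(nm) prob_point(params, nm)
  cost <- function(nm) cost_amount(params, nm)
  ann <- function(nm) lifetime_to_annual(p(nm), nc)

  base_oneoff <- cost("counseling") + cost("ngs_plus_mlpa")
  screen <- cost("screening_mutation_carrier_annual")

  carrier_arms <- function(gene) {
    w_gene <- p(paste0("p_relative_", gene))
    a_mx <- p("p_adhere_mastectomy")
    a_rrso <- p("p_adhere_rrso")
    risk <- function(site, suffix) ann(paste0("p_", site, "_ca_", gene, suffix))
    data.frame(
      label = paste0(gene, c("_both", "_rrso_only", "_mx_only", "_no_surgery")),
      weight = w_gene * c(a_mx * a_rrso,
                          (1 - a_mx) * a_rrso,
                          a_mx * (1 - a_rrso),
                          (1 - a_mx) * (1 - a_rrso)),
      p_breast_annual = c(risk("breast", "_post_both"),
                          risk("breast", "_post_rrso"),
                          risk("breast", "_post_mx"),
                          risk("breast", "")),
      p_ovarian_annual = c(risk("ov", "_post_rrso"),
                           risk("ov", "_post_rrso"),
                           risk("ov", ""),
                           risk("ov", "")),
      oneoff_cost = base_oneoff +
        c(cost("mastectomy") + cost("rrso"), cost("rrso"), cost("mastectomy"), 0),
      # breast screening only for carriers who refuse mastectomy
      percycle_cost = c(0, screen, 0, screen),
      stringsAsFactors = FALSE
    )
  }

  no_mut <- data.frame(
    label = "no_mutation",
    weight = 1 - p("p_relative_brca1") - p("p_relative_brca2"),
    p_breast_annual = ann("p_breast_ca_nomut"),
    p_ovarian_annual = ann("p_ov_ca_nomut"),
    oneoff_cost = base_oneoff,
    percycle_cost = 0,
    stringsAsFactors = FALSE
  )

  arms <- rbind(carrier_arms("brca1"), carrier_arms("brca2"), no_mut)
  new_strategy("testing_plus_prophylaxis", arms)
}

#' Build the usual-care comparator strategy
#'
#' Same latent carrier mixture as the testing strategy, but no genetic
#' testing and no risk-reducing surgery: carriers keep their unmodified
#' penetrance.  The only cost is annual breast screening for relatives the
#' risk algorithm flags as high-risk, applied as its expected value
#' `p_high_risk_algorithm * screening_mutation_carrier_annual`
#' (0.24 x R$333.75 = R$80.10 per cycle) uniformly across arms while
#' cancer-free.
#'
#' @inheritParams build_testing_strategy
#' @return A `cea_strategy` object.
#' @export
build_usual_care_strategy <- function(params) {
  violations <- validate_parameters(params)
  if (length(violations) > 0L) {
    stop("cannot build strategy from invalid parameters:\n  ",
         paste(violations, collapse = "\n  "), call. = FALSE)
  }
  nc <- n_cycles(params)
  p <- function(nm) prob_point(params, nm)
  ann <- function(nm) lifetime_to_annual(p(nm), nc)
  screen_expected <- expected_screening_cost(
    p("p_high_risk_algorithm"),
    cost_amount(params, "screening_mutation_carrier_annual"))

  arms <- data.frame(
    label = c("brca1_untested", "brca2_untested", "no_mutation"),
    weight = c(p("p_relative_brca1"), p("p_relative_brca2"),
               1 - p("p_relative_brca1") - p("p_relative_brca2")),
    p_breast_annual = c(ann("p_breast_ca_brca1"), ann("p_breast_ca_brca2"),
                        ann("p_breast_ca_nomut")),
    p_ovarian_annual = c(ann("p_ov_ca_brca1"), ann("p_ov_ca_brca2"),
                         ann("p_ov_ca_nomut")),
    oneoff_cost = 0,
    percycle_cost = screen_expected,
    stringsAsFactors = FALSE
  )
  new_strategy("usual_care", arms)
}

#' Arm table of a strategy
#'
#' @param x A `cea_strategy` object.
#' @param ... Unused.
#' @return The arm table as a data frame (label, weight, annual risks,
#'   one-off and per-cycle costs).
#' @export
as.data.frame.cea_strategy <- function(x, ...) x$arms

#' Write a strategy's arm table as CSV (debug dump)
#'
#' @param strategy A `cea_strategy` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_arm_table <- function(strategy, path) {
  utils::write.csv(strategy$arms, path, row.names = FALSE)
  invisible(path)
}

#' @export
print.cea_strategy <- function(x, ...) {
  cat(sprintf("<cea_strategy> %s: %d arms\n", x$name, nrow(x$arms)))
  print(x$arms, row.names = FALSE, digits = 6)
  invisible(x)
}
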
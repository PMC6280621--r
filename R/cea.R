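#' Incremental cost-effectiveness ratio with dominance logic
#'
#' Computes `delta_cost = c1 - c0`, `delta_eff = e1 - e0` and, when the
#' deltas indicate a genuine trade-off, their ratio.  A cheaper and more
#' effective intervention is `dominant`; a costlier and less effective one
#' is `dominated`; equal effectiveness yields no ratio (`no_ratio`).  The
#' headline comparison of this model lands in quadrant I (costlier, more
#' effective), where the ICER is cost per unit of effectiveness gained.
#'
#' @param c1,e1 Cost and effectiveness of the intervention.
#' @param c0,e0 Cost and effectiveness of the comparator.
#' @return A `cea_icer` list: `delta_cost`, `delta_eff`, `icer` (NA when
#'   undefined), `status` (one of `"icer"`, `"dominant"`, `"dominated"`,
#'   `"no_ratio"`).
#' @examples
#' icer(1241.22, 16.13, 78.96, 14.85)$icer  # 908.015625
#' icer(10, 2, 20, 1)$status                # "dominant"
#' @export
icer <- function(c1, e1, c0, e0) {
  vals <- c(c1, e1, c0, e0)
  if (!is.numeric(vals) || any(!is.finite(vals))) {
    stop("icer() requires finite numeric inputs", call. = FALSE)
  }
  dc <- c1 - c0
  de <- e1 - e0
  status <- if (de == 0) {
    "no_ratio"
  } else if (de > 0 && dc <= 0) {
    "dominant"
  } else if (de < 0 && dc >= 0) {
    "dominated"
  } else {
    "icer"
  }
  structure(list(delta_cost = dc, delta_eff = de,
                 icer = if (status == "icer") dc / de else NA_real_,
                 status = status),
            class = "cea_icer")
}

#' Classify an ICER against the willingness-to-pay thresholds
#'
#' Compares a cost-per-case-prevented figure with the two reference
#' thresholds (R$7,543.50 and R$23,786.70 at the defaults).  Boundaries are
#' inclusive: a value exactly at a threshold gets the classification of the
#' band it closes.
#'
#' @param icer_value ICER in BRL per case prevented.
#' @param params A `cea_parameters` object supplying `threshold_low` and
#'   `threshold_high`.
#' @return One of `"cost_effective_low"`, `"cost_effective_high"`,
#'   `"not_cost_effective"`.
#' @export
classify_icer <- function(icer_value, params) {
  stopifnot(is.finite(icer_value))
  lo <- params$structure$threshold_low
  hi <- params$structure$threshold_high
  if (icer_value < lo) "cost_effective_low"
  else if (icer_value <= hi) "cost_effective_high"
  else "not_cost_effective"
}

#' Annual number of relatives eligible for cascade testing
#'
#' Population arithmetic preceding a budget-impact analysis: annual
#' ovarian-cancer incidence times the proportion of cases with a germline
#' mutation times first-degree female relatives per patient times the
#' transmission probability, rounded to a whole count.
#'
#' @param cases_per_year Annual ovarian-cancer case count (6,150 at default).
#' @param prop_mutation Proportion of cases with a BRCA1/2 germline mutation
#'   (0.19 at default).
#' @param relatives_per_patient First-degree female relatives per patient
#'   (3.5 at default).
#' @param transmission Mutation transmission probability (0.5).
#' @return Rounded integer count of eligible relatives per year.
#' @examples
#' eligible_population(6150, 0.19, 3.5, 0.5)  # 2045
#' @export
eligible_population <- function(cases_per_year, prop_mutation,
                                relatives_per_patient, transmission) {
  stopifnot(cases_per_year >= 0, prop_mutation >= 0,
            relatives_per_patient >= 0, transmission >= 0)
  round(cases_per_year * prop_mutation * relatives_per_patient * transmission)
}

#' Expected annual screening cost for untested relatives
#'
#' Under usual care only relatives flagged by the risk algorithm (predicted
#' mutation probability >= 10%) are screened, so the expected per-relative
#' annual cost is the product of the high-risk probability and the annual
#' screening cost: 0.24 x R$333.75 = R$80.10 at the defaults.
#'
#' @param p_high_risk Probability a relative is flagged high-risk.
#' @param annual_cost Annual screening cost in BRL.
#' @return Expected cost in BRL per relative per year.
#' @export
expected_screening_cost <- function(p_high_risk, annual_cost) {
  stopifnot(p_high_risk >= 0, p_high_risk <= 1, annual_cost >= 0)
  p_high_risk * annual_cost
}

#' Full cost-effectiveness analysis at a parameter set
#'
#' Builds both strategies, runs the cohort engine over the parameter set's
#' age horizon with its discount rate, and composes the incremental
#' comparison and threshold classification.  Deterministic given the
#' parameters.
#'
#' @param params A `cea_parameters` object.
#' @param convention Effectiveness convention passed to
#'   [strategy_outcome()].
#' @param cohort_size Optional joint rescaling of costs and effects (e.g.
#'   100 to report per-100-relatives); the ICER is invariant to it.
#' @return A `cea_result` list: both `cea_outcome`s, deltas, `icer`,
#'   `status`, `classification`, thresholds, convention and the parameter
#'   fingerprint.
#' @examples
#' res <- full_analysis(load_parameters())
#' res$classification  # "cost_effective_low"
#' @export
full_analysis <- function(params, convention = c("per100", "person_years"),
                          cohort_size = 1) {
  convention <- match.arg(convention)
  stopifnot(cohort_size > 0)
  nc <- n_cycles(params)
  rate <- params$structure$discount_rate

  out1 <- strategy_outcome(run_cohort(build_testing_strategy(params), nc, rate),
                           convention)
  out0 <- strategy_outcome(run_cohort(build_usual_care_strategy(params), nc, rate),
                           convention)

  inc <- icer(out1$expected_cost * cohort_size, out1$effectiveness * cohort_size,
              out0$expected_cost * cohort_size, out0$effectiveness * cohort_size)
  classification <- switch(inc$status,
    icer = classify_icer(inc$icer, params),
    dominant = "dominant",
    dominated = "dominated",
    no_ratio = "no_ratio"
  )
  structure(list(
    intervention = out1,
    comparator = out0,
    delta_cost = inc$delta_cost,
    delta_eff = inc$delta_eff,
    icer = inc$icer,
    status = inc$status,
    classification = classification,
    threshold_low = params$structure$threshold_low,
    threshold_high = params$structure$threshold_high,
    convention = convention,
    cohort_size = cohort_size,
    parameter_fingerprint = parameter_fingerprint(params)
  ), class = "cea_result")
}

#' Serialise a CEA result document to JSON
#'
#' @param result A `cea_result` object.
#' @param path Output path.
#' @param microsim Optional `microsim_estimate` (or list of them) to embed.
#' @return `path`, invisibly.
#' @export
write_result_json <- function(result, path, microsim = NULL) {
  doc <- list(
    strategies = list(
      intervention = unclass(result$intervention),
      comparator = unclass(result$comparator)
    ),
    delta_cost = result$delta_cost,
    delta_eff = result$delta_eff,
    icer = result$icer,
    status = result$status,
    classification = result$classification,
    thresholds = list(low = result$threshold_low, high = result$threshold_high),
    effectiveness_convention = result$convention,
    cohort_size = result$cohort_size,
    parameter_fingerprint = result$parameter_fingerprint
  )
  if (!is.null(microsim)) {
    doc$microsim <- if (inherits(microsim, "microsim_estimate")) {
      unclass(microsim)
    } else {
      lapply(microsim, unclass)
    }
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(path)
}

#' @export
print.cea_icer <- function(x, ...) {
  cat("<cea_icer>", x$status, "\n")
  cat(sprintf("  delta cost: R$%.2f, delta effectiveness: %.4f\n",
              x$delta_cost, x$delta_eff))
  if (x$status == "icer") cat(sprintf("  ICER: R$%.2f per unit effectiveness\n", x$icer))
  invisible(x)
}

#' @export
print.cea_result <- function(x, ...) {
  cat("<cea_result>\n")
  cat(sprintf("  %-26s cost R$%10.2f  effectiveness %8.4f (%s)\n",
              x$intervention$strategy, x$intervention$expected_cost,
              x$intervention$effectiveness, x$convention))
  cat(sprintf("  %-26s cost R$%10.2f  effectiveness %8.4f\n",
              x$comparator$strategy, x$comparator$expected_cost,
              x$comparator$effectiveness))
  cat(sprintf("  delta: R$%.2f / %.4f", x$delta_cost, x$delta_eff))
  if (x$status == "icer") {
    cat(sprintf("  ->  ICER R$%.2f", x$icer))
  } else {
    cat("  -> ", x$status)
  }
  cat(sprintf("\n  classification: %s (thresholds R$%.2f / R$%.2f)\n",
              x$classification, x$threshold_low, x$threshold_high))
  invisible(x)
}
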
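#' Run the full analysis pipeline and write its artifacts
#'
#' Executes [full_analysis()], optionally the one-way sensitivity sweep and
#' the microsimulation oracle, and writes a JSON result document plus CSV
#' traces into `out_dir`.  Existing files are never silently overwritten.
#'
#' @param params_path Parameter file path, or `"default"`.
#' @param out_dir Output directory (created if absent).
#' @param convention Effectiveness convention (see [strategy_outcome()]).
#' @param dsa Run the one-way deterministic sensitivity analysis?
#' @param microsim_n Number of microsimulated individuals (0 skips the
#'   microsimulation).
#' @param seed Seed for the microsimulation.
#' @param export_traces Write per-cycle cohort traces and arm tables as CSV?
#' @param export_trajectories Write the per-individual trajectory CSV?
#' @param overwrite Allow overwriting existing output files?
#' @return The result document (a list), invisibly.
#' @export
run_cea_pipeline <- function(params_path = "default", out_dir,
                             convention = c("per100", "person_years"),
                             dsa = TRUE, microsim_n = 0L, seed = 1L,
                             export_traces = FALSE,
                             export_trajectories = FALSE,
                             overwrite = FALSE) {
  convention <- match.arg(convention)
  params <- load_parameters(params_path)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  out_path <- function(name) {
    p <- file.path(out_dir, name)
    if (file.exists(p) && !overwrite) {
      stop("refusing to overwrite existing file (use overwrite = TRUE): ", p,
           call. = FALSE)
    }
    p
  }

  message("parameter fingerprint: ", parameter_fingerprint(params))
  result <- full_analysis(params, convention)

  microsim <- NULL
  if (microsim_n > 0L) {
    nc <- n_cycles(params)
    rate <- params$structure$discount_rate
    message("microsimulation: n = ", microsim_n, ", seed = ", seed)
    microsim <- list(
      intervention = simulate_relatives(build_testing_strategy(params),
                                        microsim_n, seed, nc, rate,
                                        return_trajectories = export_trajectories),
      comparator = simulate_relatives(build_usual_care_strategy(params),
                                      microsim_n, seed + 1L, nc, rate,
                                      return_trajectories = export_trajectories)
    )
    if (export_trajectories) {
      for (nm in names(microsim)) {
        write_trajectories(microsim[[nm]], out_path(paste0("trajectories_", nm, ".csv")))
        microsim[[nm]]$trajectories <- NULL
      }
    }
  }

  tornado <- NULL
  if (dsa) {
    tornado <- one_way_dsa(params, convention)
    write_tornado_csv(tornado, out_path("tornado.csv"))
  }

  if (export_traces) {
    nc <- n_cycles(params)
    rate <- params$structure$discount_rate
    for (build in list(build_testing_strategy, build_usual_care_strategy)) {
      strat <- build(params)
      write_trace_csv(run_cohort(strat, nc, rate),
                      out_path(paste0("trace_", strat$name, ".csv")))
      write_arm_table(strat, out_path(paste0("arms_", strat$name, ".csv")))
    }
  }

  write_result_json(result, out_path("analysis.json"), microsim = microsim)

  doc <- list(
    result = result,
    tornado = tornado,
    microsim = microsim,
    eligible_relatives = eligible_population(
      params$structure$annual_ov_cancer_cases,
      params$structure$prevalence_brca1_patients +
        params$structure$prevalence_brca2_patients,
      params$structure$relatives_per_patient,
      params$structure$transmission_prob),
    params = params
  )
  invisible(doc)
}

#' Render a human-readable summary of a pipeline run
#'
#' @param doc Result document returned by [run_cea_pipeline()].
#' @param top_n Number of tornado entries to show.
#' @return Character vector of markdown lines (also printable with `cat`).
#' @export
render_report <- function(doc, top_n = 5L) {
  for (field in c("result", "eligible_relatives")) {
    if (is.null(doc[[field]])) {
      stop("malformed result document: missing field `", field, "`",
           call. = FALSE)
    }
  }
  res <- doc$result
  lines <- c(
    "# Cascade-testing cost-effectiveness report",
    "",
    "## Strategy outcomes (per relative, discounted)",
    sprintf("- %s: cost R$%.2f, effectiveness %.4f (%s)",
            res$intervention$strategy, res$intervention$expected_cost,
            res$intervention$effectiveness, res$convention),
    sprintf("- %s: cost R$%.2f, effectiveness %.4f",
            res$comparator$strategy, res$comparator$expected_cost,
            res$comparator$effectiveness),
    "",
    "## Incremental comparison",
    sprintf("- delta cost R$%.2f, delta effectiveness %.4f",
            res$delta_cost, res$delta_eff),
    if (res$status == "icer") {
      sprintf("- ICER: R$%.2f per unit effectiveness", res$icer)
    } else {
      sprintf("- no ICER: %s", res$status)
    },
    sprintf("- verdict: %s (thresholds R$%.2f / R$%.2f per case prevented)",
            res$classification, res$threshold_low, res$threshold_high),
    "",
    "## Sensitivity analysis"
  )
  if (is.null(doc$tornado)) {
    lines <- c(lines, "- not run")
  } else {
    top <- utils::head(as.data.frame(doc$tornado), top_n)
    lines <- c(lines, sprintf(
      "- %s: ICER %.2f (low %.3g) to %.2f (high %.3g), spread %.2f",
      top$parameter, top$icer_low, top$low, top$icer_high, top$high, top$spread))
  }
  lines <- c(lines, "", "## Microsimulation oracle")
  if (is.null(doc$microsim)) {
    lines <- c(lines, "- not run")
  } else {
    for (nm in names(doc$microsim)) {
      ms <- doc$microsim[[nm]]
      lines <- c(lines, sprintf(
        "- %s (n = %d, seed = %d): mean cost R$%.2f (SE %.3f), mean cases %.5f (SE %.5f)",
        ms$strategy, ms$n, ms$seed, ms$mean_cost, ms$se_cost,
        ms$mean_cases, ms$se_cases))
    }
  }
  c(lines, "", "## Population arithmetic",
    sprintf("- eligible first-degree relatives per year: %d",
            doc$eligible_relatives))
}
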
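#' @keywords internal
"_PACKAGE"

## Canonical parameter names: loading fails loudly if any is missing.
.required_prob_names <- c(
  "p_relative_brca1", "p_relative_brca2",
  "p_adhere_mastectomy", "p_adhere_rrso",
  "p_breast_ca_brca1", "p_breast_ca_brca2", "p_breast_ca_nomut",
  "p_ov_ca_brca1", "p_ov_ca_brca2", "p_ov_ca_nomut",
  "p_breast_ca_brca1_post_mx", "p_breast_ca_brca2_post_mx",
  "p_breast_ca_brca1_post_rrso", "p_breast_ca_brca2_post_rrso",
  "p_breast_ca_brca1_post_both", "p_breast_ca_brca2_post_both",
  "p_ov_ca_brca1_post_rrso", "p_ov_ca_brca2_post_rrso",
  "p_high_risk_algorithm"
)

.required_cost_names <- c(
  "counseling", "ngs_plus_mlpa", "mastectomy", "rrso",
  "screening_mutation_carrier_annual", "screening_high_risk_annual"
)

.required_structure_names <- c(
  "discount_rate", "age_start", "age_end",
  "prevalence_brca1_patients", "prevalence_brca2_patients",
  "threshold_low", "threshold_high",
  "annual_ov_cancer_cases", "relatives_per_patient", "transmission_prob"
)

#' Load a model parameter set
#'
#' Reads probabilities (with optional 95% sensitivity ranges), unit costs
#' (2014 BRL) and structural constants from a YAML or JSON file, validates
#' them, and returns a `cea_parameters` object.  The packaged default encodes
#' the published model inputs: mutation-carrier proportions among
#' first-degree relatives, BRCA1/2 cancer penetrance with and without
#' risk-reducing surgery, surgical adherence, and the costs of counselling,
#' NGS+MLPA testing, surgery and annual breast screening.
#'
#' @param path Path to a parameter file, or `"default"` for the packaged
#'   default parameter set.
#' @return A `cea_parameters` object: list with components `probs` (data
#'   frame: `name`, `point`, `low`, `high`, `source`), `costs` (data frame:
#'   `name`, `amount`, `recurrence`) and `structure` (named list of scalars).
#' @examples
#' params <- load_parameters()
#' prob_point(params, "p_relative_brca1")   # 0.45
#' cost_amount(params, "ngs_plus_mlpa")     # 683.61
#' @export
load_parameters <- function(path = "default") {
  if (identical(path, "default")) {
    path <- system.file("extdata", "default_parameters.yaml",
                        package = "cascadecea", mustWork = TRUE)
  }
  if (!file.exists(path)) {
    stop("parameter file not found: ", path, call. = FALSE)
  }
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  params <- parameters_from_list(raw)
  violations <- validate_parameters(params)
  if (length(violations) > 0L) {
    stop("invalid parameter set:\n  ",
         paste(violations, collapse = "\n  "), call. = FALSE)
  }
  params
}

#' @rdname load_parameters
#' @export
default_parameters <- function() load_parameters("default")

## Build a cea_parameters object from the parsed file representation.
parameters_from_list <- function(raw) {
  for (block in c("probabilities", "costs", "structure")) {
    if (is.null(raw[[block]])) {
      stop("parameter file is missing the `", block, "` map", call. = FALSE)
    }
  }
  missing_probs <- setdiff(.required_prob_names, names(raw$probabilities))
  missing_costs <- setdiff(.required_cost_names, names(raw$costs))
  missing_struct <- setdiff(.required_structure_names, names(raw$structure))
  missing <- c(missing_probs, missing_costs, missing_struct)
  if (length(missing) > 0L) {
    stop("missing required parameter(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }

  num_or_na <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)
  probs <- do.call(rbind, lapply(names(raw$probabilities), function(nm) {
    p <- raw$probabilities[[nm]]
    data.frame(name = nm,
               point = as.numeric(p$point),
               low = num_or_na(p$low),
               high = num_or_na(p$high),
               source = if (is.null(p$source)) NA_character_ else p$source,
               stringsAsFactors = FALSE)
  }))
  costs <- do.call(rbind, lapply(names(raw$costs), function(nm) {
    cst <- raw$costs[[nm]]
    data.frame(name = nm,
               amount = as.numeric(cst$amount),
               recurrence = as.character(cst$recurrence),
               stringsAsFactors = FALSE)
  }))
  structure_list <- lapply(raw$structure, as.numeric)

  obj <- list(probs = probs, costs = costs, structure = structure_list)
  class(obj) <- "cea_parameters"
  obj
}

#' Validate a parameter set
#'
#' Checks every type invariant and returns a character vector of violations
#' (empty when the set is valid).  Violations are returned, never raised, so
#' callers can report them all at once.
#'
#' @param params A `cea_parameters` object.
#' @return Character vector of human-readable violations; `character(0)` if
#'   the set is valid.
#' @export
validate_parameters <- function(params) {
  v <- character(0)
  pr <- params$probs
  for (i in seq_len(nrow(pr))) {
    nm <- pr$name[i]
    pt <- pr$point[i]
    if (!is.finite(pt) || pt < 0 || pt > 1) {
      v <- c(v, sprintf("%s: point %.4g violates 0 <= point <= 1", nm, pt))
    }
    lo <- pr$low[i]; hi <- pr$high[i]
    if (xor(is.na(lo), is.na(hi))) {
      v <- c(v, sprintf("%s: range must give both low and high or neither", nm))
    } else if (!is.na(lo)) {
      if (lo < 0 || hi > 1) {
        v <- c(v, sprintf("%s: range [%.4g, %.4g] outside [0, 1]", nm, lo, hi))
      }
      if (lo > pt) v <- c(v, sprintf("%s: low %.4g violates low <= point %.4g", nm, lo, pt))
      if (hi < pt) v <- c(v, sprintf("%s: high %.4g violates point %.4g <= high", nm, hi, pt))
    }
  }
  co <- params$costs
  for (i in seq_len(nrow(co))) {
    if (!is.finite(co$amount[i]) || co$amount[i] < 0) {
      v <- c(v, sprintf("%s: amount %.4g violates amount >= 0", co$name[i], co$amount[i]))
    }
    if (!co$recurrence[i] %in% c("one-off", "per-cycle")) {
      v <- c(v, sprintf("%s: recurrence '%s' is not 'one-off' or 'per-cycle'",
                        co$name[i], co$recurrence[i]))
    }
  }
  st <- params$structure
  if (st$age_end <= st$age_start) {
    v <- c(v, sprintf("structure: age_end %.4g must exceed age_start %.4g",
                      st$age_end, st$age_start))
  }
  if (st$discount_rate < 0) v <- c(v, "structure: discount_rate must be >= 0")
  for (nm in c("prevalence_brca1_patients", "prevalence_brca2_patients",
               "transmission_prob")) {
    if (st[[nm]] < 0 || st[[nm]] > 1) {
      v <- c(v, sprintf("structure: %s %.4g outside [0, 1]", nm, st[[nm]]))
    }
  }
  v
}

#' Write a parameter set back to disk
#'
#' Serialises a `cea_parameters` object to the same YAML (or JSON) schema
#' that [load_parameters()] reads, so that load-write-load round-trips are
#' lossless.
#'
#' @param params A `cea_parameters` object.
#' @param path Output path; format chosen by extension (`.json` for JSON,
#'   anything else is written as YAML).
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path) {
  raw <- list(
    probabilities = stats::setNames(lapply(seq_len(nrow(params$probs)), function(i) {
      row <- params$probs[i, ]
      out <- list(point = row$point)
      if (!is.na(row$low)) { out$low <- row$low; out$high <- row$high }
      if (!is.na(row$source)) out$source <- row$source
      out
    }), params$probs$name),
    costs = stats::setNames(lapply(seq_len(nrow(params$costs)), function(i) {
      list(amount = params$costs$amount[i],
           recurrence = params$costs$recurrence[i])
    }), params$costs$name),
    structure = params$structure
  )
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(raw, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    yaml::write_yaml(raw, path, precision = 12)
  }
  invisible(path)
}

#' Look up a probability point estimate by name
#'
#' @param params A `cea_parameters` object.
#' @param name Canonical probability name (e.g. `"p_ov_ca_brca1"`).
#' @return The point estimate as a numeric scalar.
#' @export
prob_point <- function(params, name) {
  i <- match(name, params$probs$name)
  if (is.na(i)) stop("unknown probability parameter: ", name, call. = FALSE)
  params$probs$point[i]
}

#' Look up a unit cost by name
#'
#' @param params A `cea_parameters` object.
#' @param name Canonical cost name (e.g. `"mastectomy"`).
#' @return The amount in 2014 BRL as a numeric scalar.
#' @export
cost_amount <- function(params, name) {
  i <- match(name, params$costs$name)
  if (is.na(i)) stop("unknown cost parameter: ", name, call. = FALSE)
  params$costs$amount[i]
}

#' Replace a probability point estimate
#'
#' Returns a modified copy; the input is never mutated (the sensitivity
#' sweep relies on this purity).
#'
#' @param params A `cea_parameters` object.
#' @param name Canonical probability name.
#' @param value New point estimate.
#' @return A new `cea_parameters` object.
#' @export
set_prob_point <- function(params, name, value) {
  i <- match(name, params$probs$name)
  if (is.na(i)) stop("unknown probability parameter: ", name, call. = FALSE)
  params$probs$point[i] <- value
  params
}

#' @rdname set_prob_point
#' @export
set_cost_amount <- function(params, name, value) {
  i <- match(name, params$costs$name)
  if (is.na(i)) stop("unknown cost parameter: ", name, call. = FALSE)
  params$costs$amount[i] <- value
  params
}

#' Number of annual model cycles implied by the age horizon
#'
#' @param params A `cea_parameters` object.
#' @return Integer number of one-year cycles (`age_end - age_start`; 40 at
#'   the defaults, ages 30 to 70).
#' @export
n_cycles <- function(params) {
  as.integer(params$structure$age_end - params$structure$age_start)
}

#' Fingerprint of a parameter set
#'
#' MD5 digest of the canonical JSON serialisation, recorded in result
#' documents so a reported ICER can be traced to the exact inputs.
#'
#' @param params A `cea_parameters` object.
#' @return Character MD5 hash.
#' @export
parameter_fingerprint <- function(params) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  write_parameters(params, tmp)
  unname(tools::md5sum(tmp))
}

#' @export
print.cea_parameters <- function(x, ...) {
  cat("<cea_parameters>\n")
  cat(sprintf("  %d probabilities (%d with sensitivity ranges), %d costs\n",
              nrow(x$probs), sum(!is.na(x$probs$low)), nrow(x$costs)))
  cat(sprintf("  horizon: ages %g-%g (%d annual cycles), discount rate %.0f%%\n",
              x$structure$age_start, x$structure$age_end, n_cycles(x),
              100 * x$structure$discount_rate))
  cat(sprintf("  thresholds: R$%.2f / R$%.2f per case prevented\n",
              x$structure$threshold_low, x$structure$threshold_high))
  invisible(x)
}
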
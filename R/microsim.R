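utils::globalVariables(c("xmin", "xmax", "parameter"))

#' Individual-level Monte-Carlo microsimulation
#'
#' Independent oracle for the cohort engine: simulates `n` relatives, each
#' first assigned to a strategy arm by the arm weights, then evolved by
#' annual Bernoulli draws with exactly the same transition probabilities,
#' cost schedule, discounting and tie-break convention as [run_cohort()].
#'
#' Randomness is reproducible bit-for-bit for a fixed seed: the seed
#' initialises one RNG stream from which the draws are consumed in a fixed
#' counter order (first the `n` arm-assignment uniforms, then one uniform
#' per individual per cycle in cycle-major order, drawn for every individual
#' whether or not already absorbed so draw positions never depend on
#' history).  A single uniform decides each cycle's transition:
#' `u < p_b` is a breast-cancer transition (the joint-mass tie-break),
#' `p_b <= u < p_b + p_o (1 - p_b)` an ovarian one.
#'
#' @param strategy A `cea_strategy` object.
#' @param n Number of simulated individuals (>= 2).
#' @param seed Integer seed.
#' @param n_cycles Number of annual cycles.
#' @param rate Annual discount rate.
#' @param return_trajectories If `TRUE`, attach a per-individual data frame
#'   (arm, terminal state, case cycle, discounted cost).
#' @return A `microsim_estimate`: `n`, `seed`, `mean_cost`, `se_cost`,
#'   `mean_cases` (discounted), `se_cases`, and optionally `trajectories`.
#' @export
simulate_relatives <- function(strategy, n, seed, n_cycles = 40L, rate = 0.05,
                               return_trajectories = FALSE) {
  stopifnot(inherits(strategy, "cea_strategy"), n >= 2L, n_cycles >= 1L)
  arms <- strategy$arms
  n_arms <- nrow(arms)

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(as.integer(seed))

  # arm assignment by inverse-CDF on one uniform per individual
  cw <- cumsum(arms$weight)
  arm <- findInterval(stats::runif(n), c(0, cw[-n_arms]))

  pb <- arms$p_breast_annual[arm]
  po <- arms$p_ovarian_annual[arm]
  thr_breast <- pb                       # joint mass to breast
  thr_exit <- pb + po * (1 - pb)
  percycle <- arms$percycle_cost[arm]

  state <- rep(1L, n)                    # 1 well, 2 breast, 3 ovarian
  cost <- arms$oneoff_cost[arm]          # one-off at cycle 0, undiscounted
  case_disc <- numeric(n)
  case_cycle <- rep(NA_integer_, n)

  for (t in 0:(n_cycles - 1L)) {
    u <- stats::runif(n)                 # drawn for all, absorbed or not
    well <- state == 1L
    cost[well] <- cost[well] + percycle[well] * discount_factor(rate, t)
    new_breast <- well & u < thr_breast
    new_ovarian <- well & !new_breast & u < thr_exit
    newly <- new_breast | new_ovarian
    state[new_breast] <- 2L
    state[new_ovarian] <- 3L
    case_disc[newly] <- discount_factor(rate, t + 1L)
    case_cycle[newly] <- t
  }

  est <- list(
    strategy = strategy$name,
    n = as.integer(n),
    seed = as.integer(seed),
    mean_cost = mean(cost),
    se_cost = stats::sd(cost) / sqrt(n),
    mean_cases = mean(case_disc),
    se_cases = stats::sd(case_disc) / sqrt(n)
  )
  if (return_trajectories) {
    states <- c("well", "breast_cancer", "ovarian_cancer")
    est$trajectories <- data.frame(
      individual = seq_len(n),
      arm = arms$label[arm],
      terminal_state = states[state],
      case_cycle = case_cycle,
      disc_cost = cost,
      disc_case = case_disc,
      stringsAsFactors = FALSE
    )
  }
  class(est) <- "microsim_estimate"
  est
}

#' Write simulated trajectories as CSV
#'
#' One row per individual (arm, terminal state, case cycle, discounted cost
#' and case weight); round-trippable through [read_trajectories()].
#'
#' @param trajectories Data frame as attached by
#'   `simulate_relatives(..., return_trajectories = TRUE)`, or a
#'   `microsim_estimate` carrying one.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(trajectories, path) {
  if (inherits(trajectories, "microsim_estimate")) {
    trajectories <- trajectories$trajectories
    if (is.null(trajectories)) {
      stop("estimate carries no trajectories; rerun with return_trajectories = TRUE",
           call. = FALSE)
    }
  }
  utils::write.csv(trajectories, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectories
#' @export
read_trajectories <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(individual = "integer", arm = "character",
                                 terminal_state = "character",
                                 case_cycle = "integer",
                                 disc_cost = "numeric", disc_case = "numeric"))
}

#' @export
print.microsim_estimate <- function(x, ...) {
  cat(sprintf("<microsim_estimate> %s: n = %d, seed = %d\n",
              x$strategy, x$n, x$seed))
  cat(sprintf("  mean cost:  R$%.2f (SE %.3f)\n", x$mean_cost, x$se_cost))
  cat(sprintf("  mean cases: %.5f (SE %.5f, discounted)\n",
              x$mean_cases, x$se_cases))
  invisible(x)
}
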
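#' Convert a cumulative risk to an annual transition probability
#'
#' Bridges cumulative (e.g. lifetime-to-age-70) cancer penetrance and the
#' per-cycle transition probabilities of an annual-cycle state-transition
#' model, assuming a constant hazard over the span:
#' `p_annual = 1 - (1 - p_lifetime)^(1/n_years)`.
#'
#' @param p_lifetime Cumulative probability over the whole span, in `[0, 1)`.
#' @param n_years Length of the span in years (positive integer).
#' @return Annual probability in `[0, 1)`.  Vectorised over `p_lifetime`.
#' @examples
#' lifetime_to_annual(0.40, 40)           # 0.0126894...
#' annual_to_lifetime(lifetime_to_annual(0.40, 40), 40)  # 0.40
#' @export
lifetime_to_annual <- function(p_lifetime, n_years) {
  stopifnot(is.numeric(p_lifetime), is.numeric(n_years), length(n_years) == 1L)
  if (n_years < 1 || n_years != round(n_years)) {
    stop("n_years must be a positive integer", call. = FALSE)
  }
  if (any(p_lifetime < 0) || any(p_lifetime >= 1)) {
    stop("p_lifetime must lie in [0, 1): a certain event has no finite annual hazard",
         call. = FALSE)
  }
  1 - (1 - p_lifetime)^(1 / n_years)
}

#' @rdname lifetime_to_annual
#' @param p_annual Annual probability in `[0, 1)`.
#' @export
annual_to_lifetime <- function(p_annual, n_years) {
  stopifnot(is.numeric(p_annual), is.numeric(n_years), length(n_years) == 1L)
  if (n_years < 1 || n_years != round(n_years)) {
    stop("n_years must be a positive integer", call. = FALSE)
  }
  if (any(p_annual < 0) || any(p_annual >= 1)) {
    stop("p_annual must lie in [0, 1)", call. = FALSE)
  }
  1 - (1 - p_annual)^n_years
}
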
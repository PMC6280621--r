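#' One-way deterministic sensitivity analysis (tornado data)
#'
#' For every probability parameter with a published 95% range, recomputes
#' [full_analysis()] with that parameter at its low and then its high bound
#' while all others stay at their point estimates, and records the ICER
#' excursion.  Parameters without published ranges (the carrier split, the
#' costs, the high-risk-algorithm probability) are not swept unless the user
#' supplies a range.  Entries are ranked by the absolute ICER spread,
#' descending; an excursion that destroys the quadrant-I trade-off is
#' reported through its `status_*` column rather than raised.
#'
#' @param params A `cea_parameters` object.
#' @param convention Effectiveness convention forwarded to [full_analysis()].
#' @return A `cea_tornado` data frame with columns `parameter`, `low`,
#'   `high`, `icer_low`, `icer_high`, `status_low`, `status_high`,
#'   `classification_low`, `classification_high`, `spread`, `rank`; the
#'   baseline `cea_result` is attached as attribute `"baseline"`.
#' @export
one_way_dsa <- function(params, convention = c("per100", "person_years")) {
  convention <- match.arg(convention)
  baseline <- full_analysis(params, convention)
  ranged <- params$probs$name[!is.na(params$probs$low)]

  rows <- lapply(ranged, function(nm) {
    i <- match(nm, params$probs$name)
    lo <- params$probs$low[i]
    hi <- params$probs$high[i]
    res_lo <- full_analysis(set_prob_point(params, nm, lo), convention)
    res_hi <- full_analysis(set_prob_point(params, nm, hi), convention)
    data.frame(parameter = nm, low = lo, high = hi,
               icer_low = res_lo$icer, icer_high = res_hi$icer,
               status_low = res_lo$status, status_high = res_hi$status,
               classification_low = res_lo$classification,
               classification_high = res_hi$classification,
               spread = abs(res_hi$icer - res_lo$icer),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(-tab$spread, tab$parameter), , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  attr(tab, "baseline") <- baseline
  class(tab) <- c("cea_tornado", class(tab))
  tab
}

#' Guard against stateful mutation during the sensitivity sweep
#'
#' Runs [full_analysis()] at the untouched parameter set, performs the full
#' one-way sweep, recomputes the baseline, and checks the two baselines are
#' identical bit-for-bit.  A mismatch means shared parameter state was
#' mutated by the sweep, and is raised as an error.
#'
#' @inheritParams one_way_dsa
#' @return List with `ok = TRUE`, the baseline `cea_result`, and the number
#'   of parameters swept.
#' @export
restore_check <- function(params, convention = c("per100", "person_years")) {
  convention <- match.arg(convention)
  before <- full_analysis(params, convention)
  tornado <- one_way_dsa(params, convention)
  after <- full_analysis(params, convention)
  if (!identical(before, after)) {
    stop("stateful-mutation error: baseline changed after the sensitivity sweep",
         call. = FALSE)
  }
  list(ok = TRUE, baseline = before, n_swept = nrow(tornado))
}

#' Write tornado data as CSV
#'
#' @param tornado A `cea_tornado` data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_tornado_csv <- function(tornado, path) {
  utils::write.csv(as.data.frame(tornado), path, row.names = FALSE)
  invisible(path)
}

#' Tornado diagram
#'
#' Horizontal bars spanning each parameter's low/high ICER excursion,
#' ordered by spread, with the baseline ICER as a dashed reference line.
#'
#' @param tornado A `cea_tornado` data frame from [one_way_dsa()].
#' @param top_n Plot at most this many parameters (largest spreads).
#' @return A ggplot object.
#' @export
plot_tornado <- function(tornado, top_n = 15L) {
  baseline <- attr(tornado, "baseline")
  df <- utils::head(as.data.frame(tornado), top_n)
  df$parameter <- factor(df$parameter, levels = rev(df$parameter))
  df$xmin <- pmin(df$icer_low, df$icer_high)
  df$xmax <- pmax(df$icer_low, df$icer_high)
  ggplot2::ggplot(df) +
    ggplot2::geom_segment(
      ggplot2::aes(x = xmin, xend = xmax, y = parameter, yend = parameter),
      linewidth = 4, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = baseline$icer, linetype = "dashed") +
    ggplot2::labs(x = "ICER (BRL per unit effectiveness)", y = NULL,
                  title = "One-way deterministic sensitivity analysis",
                  subtitle = sprintf("baseline ICER R$%.2f", baseline$icer)) +
    ggplot2::theme_minimal()
}
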
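# Toy strategy constructor used across tests: bypasses the parameter set so
# transition probabilities and costs can be chosen freely.
toy_strategy <- function(pb, po, weight = NULL, oneoff = 0, percycle = 0,
                         name = "toy") {
  k <- length(pb)
  if (is.null(weight)) weight <- rep(1 / k, k)
  arms <- data.frame(
    label = paste0("arm", seq_len(k)),
    weight = weight,
    p_breast_annual = pb,
    p_ovarian_annual = po,
    oneoff_cost = rep_len(oneoff, k),
    percycle_cost = rep_len(percycle, k),
    stringsAsFactors = FALSE
  )
  cascadecea:::new_strategy(name, arms)
}

# Parameter set in which prophylaxis has no effect and the intervention is
# free: post-surgery risks equal no-surgery risks, all testing / surgery /
# screening costs zero.  The two strategies must then be equivalent.
neutral_parameters <- function() {
  p <- load_parameters()
  for (gene in c("brca1", "brca2")) {
    pb <- prob_point(p, paste0("p_breast_ca_", gene))
    po <- prob_point(p, paste0("p_ov_ca_", gene))
    for (sfx in c("_post_mx", "_post_rrso", "_post_both")) {
      p <- set_prob_point(p, paste0("p_breast_ca_", gene, sfx), pb)
    }
    p <- set_prob_point(p, paste0("p_ov_ca_", gene, "_post_rrso"), po)
  }
  # ranges no longer bracket the inflated post-surgery points; drop them
  p$probs$low[grepl("_post_", p$probs$name)] <- NA_real_
  p$probs$high[grepl("_post_", p$probs$name)] <- NA_real_
  for (nm in p$costs$name) p <- set_cost_amount(p, nm, 0)
  p
}
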
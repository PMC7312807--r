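# Independent oracles used across the suite. Each re-derives the
# quantity from its definition (enumeration, closed form, brute force)
# without touching the package's implementation path.

# Benjamini-Hochberg step-up from the definition: the adjusted value of
# the i-th order statistic is min over j >= i of m * p_(j) / j, capped
# at 1.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  adj <- numeric(m)
  for (i in seq_len(m))
    adj[i] <- min(1, min(m * ps[i:m] / (i:m)))
  adj[order(ord)]
}

# Exhaustive AAFC null: score every size-k subset of the |fc| universe.
exhaustive_null_oracle <- function(afc, k) {
  scores <- as.vector(combn(afc, k, sum))
  list(draws = scores, mean = mean(scores),
       sd = sqrt(mean((scores - mean(scores))^2)))
}

# Upper-tail hypergeometric P(X >= k) by direct enumeration.
hyper_tail_oracle <- function(k, set_size, universe, n_draw) {
  j <- k:min(set_size, n_draw)
  sum(choose(set_size, j) * choose(universe - set_size, n_draw - j)) /
    choose(universe, n_draw)
}

# A small deterministic fold-change table.
toy_fc_table <- function(fc, t_p = 0.5) {
  fc_table(sprintf("g%03d", seq_along(fc)), fc, t_p = t_p)
}

# A null experiment plus one fold-change table, for calibration checks.
null_fc_table <- function(n_genes, seed, noise_sd = 0.5) {
  sim <- generate_experiment(
    simulation_config(n_genes, noise_sd = noise_sd, seed = seed))
  compute_fc(sim$experiment)
}

# Collection whose memberships come straight from simulation truth.
collection_from_truth <- function(truth) {
  module_collection(lapply(names(truth$members), function(nm) {
    cls <- truth$module_effects$class[truth$module_effects$module == nm]
    list(name = nm, class = if (length(cls)) cls[1] else NA,
         genes = truth$members[[nm]])
  }))
}
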
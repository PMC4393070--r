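# Shared in-code fixtures for the test suite.  Everything is built
# programmatically; no binary data.

# Small normalized matrix whose per-time-point dominant-label patterns are
# easy to reason about: three genes, values pinned near the label centers.
tiny_normalized <- function() {
  m <- rbind(A = c(0.20, 0.50, 0.80, 0.20),
             B = c(0.20, 0.20, 0.50, 0.20),
             C = c(0.80, 0.50, 0.20, 0.80))
  colnames(m) <- paste0("T", 1:4)
  m
}

# Raw (unnormalized) complete expression matrix with correlated genes.
random_expression <- function(n_genes = 6, n_time = 10, seed = 42) {
  cfg <- simulation_config(n_genes = n_genes, n_timepoints = n_time,
                           edge_count = n_genes, seed = seed)
  simulate_expression(generate_grn(cfg), cfg)
}

# Hand-built trained model object for rule-analysis unit tests.
fake_model <- function(genes, target, antecedents, consequents, weights,
                       mf = mf_params()) {
  ti <- match(target, genes)
  rb <- structure(list(target_gene = target,
                       input_genes = genes[-ti],
                       antecedents = antecedents,
                       consequents = consequents,
                       support = rep(1L, length(consequents)),
                       weights = weights),
                  class = "rulebase")
  structure(list(target_gene = target, input_genes = genes[-ti],
                 genes = genes, target_index = ti, rulebase = rb,
                 mf = mf, ridge = 0, lag = 0L,
                 training_mse = 0),
            class = "rbnfn")
}

# Independently shuffles each gene's series (destroys cross-gene structure
# while preserving every marginal distribution).
shuffle_rows <- function(m, seed) {
  set.seed(seed)
  out <- t(apply(m, 1L, sample))
  dimnames(out) <- dimnames(m)
  out
}

# F-score of the full pipeline against the generating network for one seed,
# optionally on the row-shuffled control matrix.
recovery_f <- function(seed, shuffle = FALSE) {
  cfg <- simulation_config(seed = seed)
  truth <- generate_grn(cfg)
  expr <- simulate_expression(truth, cfg)
  if (shuffle) expr <- shuffle_rows(expr, seed + 5000L)
  res <- infer_network(expr)
  evaluate_network(res$network, truth, universe = rownames(expr))$f_score
}
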
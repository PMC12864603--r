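# Shared test helpers: tiny model configurations, random peptides, and
# independent brute-force transcriptions of the model equations used as
# oracles. The oracles are written in the most literal style possible (scalar
# loops, no shared code with the package internals).

`%||%` <- function(a, b) if (is.null(a)) b else a

random_peptides <- function(n, min_len = 2, max_len = 50, seed = 1) {
  set.seed(seed)
  vapply(seq_len(n), function(i) {
    paste(sample(AA_ALPHABET, sample(min_len:max_len, 1), replace = TRUE),
          collapse = "")
  }, character(1))
}

tiny_seq_config <- function() {
  seq_encoder_config(model_dim = 8L, heads = 2L, ffn_mult = 2L)
}

tiny_graph_config <- function() {
  graph_encoder_config(hidden_dim = 6L, readout_dim = 8L)
}

tiny_model <- function(view = "both", seed = 1,
                       strategy = "hierarchical", dropout = 0.2) {
  aop_model(view = view, seq_config = tiny_seq_config(),
            graph_config = tiny_graph_config(),
            fusion = fusion_config(strategy = strategy, dropout = dropout),
            seed = seed)
}

tiny_manifest <- function(n_pos = 6, n_neg = 6, seed = 5, max_len = 10) {
  generate_peptides(synth_spec(n_pos, n_neg, length_range = c(3, max_len),
                               seed = seed))
}

# A hand-built molecular graph with n <= 4 atoms (no chemistry involved) for
# brute-force MPNN oracles.
toy_graph <- function(n_atoms = 4, seed = 3) {
  set.seed(seed)
  edges <- switch(as.character(n_atoms),
    "2" = rbind(c(1, 2)),
    "3" = rbind(c(1, 2), c(2, 3)),
    "4" = rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 1))
  )
  structure(
    list(
      node_features = matrix(rnorm(n_atoms * 13), n_atoms, 13),
      edges = edges,
      edge_features = matrix(rnorm(nrow(edges) * 5), nrow(edges), 5),
      n_atoms = as.integer(n_atoms),
      n_bonds = nrow(edges),
      version = FEATURIZER_VERSION
    ),
    class = "mol_graph"
  )
}

# Relabel the atoms of a mol_graph with a permutation.
permute_graph <- function(graph, perm) {
  inv <- integer(length(perm))
  inv[perm] <- seq_along(perm)
  structure(
    list(
      node_features = graph$node_features[perm, , drop = FALSE],
      edges = cbind(inv[graph$edges[, 1]], inv[graph$edges[, 2]]),
      edge_features = graph$edge_features,
      n_atoms = graph$n_atoms,
      n_bonds = graph$n_bonds,
      version = graph$version
    ),
    class = "mol_graph"
  )
}

expect_close <- function(actual, expected, tol = 1e-10) {
  expect_lt(max(abs(actual - expected)), tol)
}
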
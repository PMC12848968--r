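# Shared test helpers: tiny architectures and graph permutation.

tiny_config <- function(variant = "sd", ...) {
  model_config(variant = variant, n_message_iterations = 3L,
               node_dim = 8L, edge_dim = 6L, graph_dim = 8L,
               n_attention_heads = 2L, head_hidden = 10L, ...)
}

# Permute the node order of a mol_graph (and shuffle its edge list),
# preserving the molecule.
permute_graph <- function(g, perm = sample(g$n_heavy)) {
  g2 <- g
  inv <- order(perm)          # inv[old] = new position
  g2$nodes <- g$nodes[perm, , drop = FALSE]
  rownames(g2$nodes) <- NULL
  g2$edges$i <- inv[g$edges$i]
  g2$edges$j <- inv[g$edges$j]
  if (nrow(g2$edges) > 1) {
    eperm <- sample(nrow(g2$edges))
    g2$edges <- g2$edges[eperm, , drop = FALSE]
    rownames(g2$edges) <- NULL
  }
  g2
}

five_solvents <- c("acetonitrile", "water", "tetrahydrofuran",
                   "dimethylsulfoxide", "dimethylformamide")
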
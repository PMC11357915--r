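# Shared fixtures and independent oracles.

# path graph 1-2-3-4-5
path5 <- function() {
  as_interactome(c("1", "2", "3", "4"), c("2", "3", "4", "5"))
}

# complete graph on k labelled nodes
clique_graph <- function(k) {
  p <- utils::combn(as.character(seq_len(k)), 2)
  as_interactome(p[1, ], p[2, ])
}

# random connected Erdos-Renyi-ish graph with <= n_max nodes: draw edges,
# keep the LCC, require a minimum size
random_connected_graph <- function(n_max = 50, p = 0.12, n_min = 10) {
  repeat {
    n <- sample(n_min:n_max, 1)
    pairs <- utils::combn(n, 2)
    keep <- stats::runif(ncol(pairs)) < p
    if (sum(keep) < n - 1) next
    g <- as_interactome(as.character(pairs[1, keep]),
                        as.character(pairs[2, keep]))
    lcc <- extract_lcc(g)
    if (length(lcc$nodes) >= n_min) return(lcc)
  }
}

# igraph mirror of an interactome (independent oracle backend)
as_igraph <- function(g) {
  el <- cbind(g$nodes[g$edges[, 1]], g$nodes[g$edges[, 2]])
  ig <- igraph::graph_from_edgelist(el, directed = FALSE)
  missing <- setdiff(g$nodes, igraph::V(ig)$name)
  if (length(missing)) ig <- ig + igraph::vertices(missing)
  ig
}

# all-pairs shortest-path matrix by igraph BFS (the exhaustive oracle)
oracle_dist <- function(g) {
  ig <- as_igraph(g)
  d <- igraph::distances(ig)
  d[g$nodes, g$nodes, drop = FALSE]
}

# separation score evaluated directly from the full distance matrix
oracle_separation <- function(D, a, b) {
  internal <- function(x) {
    mean(vapply(x, function(v) min(D[v, setdiff(x, v)]), numeric(1)))
  }
  d_ab <- mean(c(vapply(a, function(v) min(D[v, b]), numeric(1)),
                 vapply(b, function(v) min(D[v, a]), numeric(1))))
  d_ab - (internal(a) + internal(b)) / 2
}

# directional closest-distance proximity from the full distance matrix
oracle_closest <- function(D, h, t) {
  mean(vapply(t, function(v) min(D[h, v]), numeric(1)))
}
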
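# Internal breadth-first-search engine. All network distances in the package
# are unweighted hop counts computed over an adjacency list (list of integer
# neighbour vectors, 1-based).

# Level-synchronous multi-source BFS: one pass gives, for every node, the hop
# distance to the closest source. NA_integer_ marks unreachable nodes.
bfs_hops <- function(adj, sources) {
  n <- length(adj)
  dist <- rep.int(NA_integer_, n)
  frontier <- unique(as.integer(sources))
  dist[frontier] <- 0L
  d <- 0L
  while (length(frontier) > 0L) {
    nb <- unlist(adj[frontier], use.names = FALSE)
    if (length(nb)) {
      nb <- unique(nb)
      nb <- nb[is.na(dist[nb])]
    }
    d <- d + 1L
    dist[nb] <- d
    frontier <- nb
  }
  dist
}

# Connected-component labels by repeated BFS.
component_labels <- function(adj) {
  n <- length(adj)
  comp <- integer(n)
  cid <- 0L
  for (v in seq_len(n)) {
    if (comp[v] == 0L) {
      cid <- cid + 1L
      comp[!is.na(bfs_hops(adj, v))] <- cid
    }
  }
  comp
}
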
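#' Build an interactome from a two-column edge table
#'
#' Constructs an undirected simple graph of protein/gene nodes. Self-loops
#' are removed and duplicate unordered pairs are collapsed, so merging the
#' same edge list twice yields the identical graph.
#'
#' @param from,to character vectors of interacting node identifiers.
#' @return An object of class `interactome`: a list with elements `nodes`
#'   (sorted character vector), `edges` (two-column integer matrix indexing
#'   `nodes`, each row ordered so the first index is the smaller) and `adj`
#'   (adjacency list of integer neighbour vectors).
#' @export
as_interactome <- function(from, to) {
  from <- as.character(from)
  to <- as.character(to)
  stopifnot(length(from) == length(to))
  ok <- !is.na(from) & !is.na(to) & nzchar(from) & nzchar(to)
  from <- from[ok]
  to <- to[ok]
  keep <- from != to                       # drop self-loops
  from <- from[keep]
  to <- to[keep]
  nodes <- sort(unique(c(from, to)))
  a <- match(from, nodes)
  b <- match(to, nodes)
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  dup <- duplicated(cbind(lo, hi))
  lo <- lo[!dup]
  hi <- hi[!dup]
  # canonical row order (nodes are sorted, so index order = label order)
  o <- order(lo, hi)
  new_interactome(nodes, cbind(lo[o], hi[o]))
}

# edges: 2-col integer matrix, rows (i, j) with i < j, unique, no self-loops
new_interactome <- function(nodes, edges) {
  n <- length(nodes)
  if (is.null(dim(edges))) edges <- matrix(edges, ncol = 2L)
  storage.mode(edges) <- "integer"
  if (nrow(edges)) {
    ii <- c(edges[, 1L], edges[, 2L])
    jj <- c(edges[, 2L], edges[, 1L])
    adj <- split(jj, factor(ii, levels = seq_len(n)))
    adj <- lapply(adj, function(v) sort(as.integer(v)))
  } else {
    adj <- rep(list(integer(0)), n)
  }
  names(adj) <- NULL
  structure(list(nodes = nodes, edges = edges, adj = adj),
            class = "interactome")
}

#' @export
print.interactome <- function(x, ...) {
  deg <- lengths(x$adj)
  ncomp <- if (length(x$nodes)) max(component_labels(x$adj)) else 0L
  cat("Interactome: ", length(x$nodes), " nodes, ", nrow(x$edges),
      " undirected edges\n", sep = "")
  if (length(deg)) {
    cat("  degree: min ", min(deg), ", median ", stats::median(deg),
        ", max ", max(deg), "\n", sep = "")
  }
  cat("  connected components: ", ncomp, "\n", sep = "")
  invisible(x)
}

#' Node degrees of an interactome
#'
#' @param graph an `interactome`.
#' @return Named integer vector of node degrees.
#' @export
node_degree <- function(graph) {
  stopifnot(inherits(graph, "interactome"))
  stats::setNames(lengths(graph$adj), graph$nodes)
}

#' Load and merge protein-protein interaction edge lists
#'
#' Reads one or more two-column TSV files (one undirected interaction per
#' row) and merges them into a single simple graph: the union of all edges,
#' deduplicated as unordered pairs, self-loops removed. Rows with missing
#' fields are skipped and counted. Per-source pair counts are kept in the
#' `"source_counts"` attribute and reported via `message()`.
#'
#' @param paths character vector of TSV file paths.
#' @param header logical; do the files carry a header row? Default `FALSE`.
#' @return An `interactome` with attributes `source_counts` (usable rows per
#'   file) and `skipped_rows` (rows dropped per file).
#' @export
load_edge_lists <- function(paths, header = FALSE) {
  stopifnot(length(paths) >= 1)
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop("edge list file(s) not found: ", paste(missing, collapse = ", "))
  }
  froms <- character(0)
  tos <- character(0)
  src_counts <- integer(length(paths))
  skipped <- integer(length(paths))
  for (k in seq_along(paths)) {
    df <- utils::read.delim(paths[k], header = header, sep = "\t",
                            colClasses = "character", quote = "",
                            comment.char = "", stringsAsFactors = FALSE)
    if (ncol(df) < 2) stop("edge list needs two columns: ", paths[k])
    f <- df[[1L]]
    t <- df[[2L]]
    ok <- !is.na(f) & !is.na(t) & nzchar(f) & nzchar(t)
    skipped[k] <- sum(!ok)
    src_counts[k] <- sum(ok)
    froms <- c(froms, f[ok])
    tos <- c(tos, t[ok])
  }
  names(src_counts) <- names(skipped) <- basename(paths)
  g <- as_interactome(froms, tos)
  attr(g, "source_counts") <- src_counts
  attr(g, "skipped_rows") <- skipped
  message("merged ", length(paths), " source(s): ", length(g$nodes),
          " nodes, ", nrow(g$edges), " unique edges (",
          sum(skipped), " malformed rows skipped)")
  g
}

#' Remap node identifiers to a canonical namespace
#'
#' Applies an identifier mapping (e.g. source database IDs to Entrez gene
#' IDs). Nodes without a mapping are dropped and counted; edges that become
#' self-loops after mapping (two nodes collapsing onto one canonical ID) are
#' removed; colliding nodes are merged with the union of their edges.
#'
#' @param graph an `interactome`.
#' @param mapping a named character vector (names = source IDs, values =
#'   canonical IDs) or a two-column data frame (source, canonical).
#' @return A remapped `interactome` with attribute `n_unmapped` and
#'   `unmapped_nodes`.
#' @export
apply_mapping <- function(graph, mapping) {
  stopifnot(inherits(graph, "interactome"))
  if (is.data.frame(mapping)) {
    stopifnot(ncol(mapping) >= 2)
    mapping <- stats::setNames(as.character(mapping[[2L]]),
                               as.character(mapping[[1L]]))
  }
  mapping <- mapping[!duplicated(names(mapping))]   # mapping is a function
  if (length(mapping) == 0) stop("empty identifier mapping")
  new_ids <- unname(mapping[graph$nodes])
  unmapped <- is.na(new_ids) | !nzchar(new_ids)
  if (any(unmapped)) {
    warning(sum(unmapped), " node(s) without mapping dropped")
  }
  if (nrow(graph$edges)) {
    f <- new_ids[graph$edges[, 1L]]
    t <- new_ids[graph$edges[, 2L]]
    keep <- !is.na(f) & !is.na(t)
    g <- as_interactome(f[keep], t[keep])
  } else {
    g <- as_interactome(character(0), character(0))
  }
  attr(g, "n_unmapped") <- sum(unmapped)
  attr(g, "unmapped_nodes") <- graph$nodes[unmapped]
  g
}

#' Extract the largest connected component
#'
#' All distance-based analyses are restricted to the largest connected
#' component (LCC) so that every pairwise distance is finite. Size ties are
#' broken towards the component containing the lexicographically smallest
#' node label, making the result deterministic.
#'
#' @param graph a non-empty `interactome`.
#' @return The node-induced subgraph on the LCC, as an `interactome`.
#' @export
extract_lcc <- function(graph) {
  stopifnot(inherits(graph, "interactome"))
  if (length(graph$nodes) == 0) stop("cannot extract LCC of an empty graph")
  comp <- component_labels(graph$adj)
  sizes <- tabulate(comp)
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    # tie: component holding the smallest node label (nodes are sorted, so
    # the smallest member index is the smallest label)
    first_member <- vapply(best, function(cid) which(comp == cid)[1L], 0L)
    best <- best[which.min(first_member)]
  }
  induced_subgraph_idx(graph, which(comp == best))
}

# Node-induced subgraph on integer node indices: no edge among retained
# nodes is gained or lost.
induced_subgraph_idx <- function(graph, idx) {
  idx <- sort(unique(as.integer(idx)))
  keep <- rep(FALSE, length(graph$nodes))
  keep[idx] <- TRUE
  e <- graph$edges
  ekeep <- keep[e[, 1L]] & keep[e[, 2L]]
  remap <- integer(length(graph$nodes))
  remap[idx] <- seq_along(idx)
  edges <- cbind(remap[e[ekeep, 1L]], remap[e[ekeep, 2L]])
  new_interactome(graph$nodes[idx], edges)
}

#' Hop distance from every node to the closest member of a source set
#'
#' Single multi-source BFS service: every node receives the minimum
#' unweighted hop distance to any source node (source nodes get 0). This is
#' the primitive behind both the separation and the proximity statistics.
#'
#' @param graph an `interactome`.
#' @param sources character vector of node identifiers; all must be present
#'   in the graph (callers are expected to pre-filter).
#' @return Named numeric vector over all nodes; `Inf` marks nodes
#'   unreachable from every source.
#' @export
nearest_set_distance <- function(graph, sources) {
  stopifnot(inherits(graph, "interactome"))
  sources <- unique(as.character(sources))
  if (length(sources) == 0) stop("empty source set")
  idx <- match(sources, graph$nodes)
  if (anyNA(idx)) {
    stop("source node(s) not in graph: ",
         paste(sources[is.na(idx)], collapse = ", "))
  }
  d <- as.numeric(bfs_hops(graph$adj, idx))
  d[is.na(d)] <- Inf
  stats::setNames(d, graph$nodes)
}

#' Hop distance from each member of a set to its closest other member
#'
#' The within-module distance primitive: for every member, the shortest-path
#' distance to a different member of the same set (self excluded). This is
#' the quantity averaged in the internal terms of the module separation
#' score.
#'
#' @param graph an `interactome`.
#' @param members character vector of node identifiers; at least two must be
#'   present in the graph.
#' @return Named numeric vector over the on-network members; `Inf` marks
#'   members unreachable from every other member.
#' @export
nearest_other_member_distance <- function(graph, members) {
  stopifnot(inherits(graph, "interactome"))
  members <- unique(as.character(members))
  idx <- match(members, graph$nodes)
  if (anyNA(idx)) {
    stop("member node(s) not in graph: ",
         paste(members[is.na(idx)], collapse = ", "))
  }
  if (length(idx) < 2) stop("need at least 2 members on the network")
  out <- vapply(seq_along(idx), function(k) {
    d <- bfs_hops(graph$adj, idx[-k])[idx[k]]
    if (is.na(d)) Inf else as.numeric(d)
  }, numeric(1))
  stats::setNames(out, members)
}

#' Fraction of a gene set present in the network
#'
#' @param graph an `interactome`.
#' @param genes non-empty character vector of gene identifiers.
#' @return Fraction in \[0, 1\] of the distinct genes found among the graph
#'   nodes.
#' @export
coverage <- function(graph, genes) {
  stopifnot(inherits(graph, "interactome"))
  genes <- unique(as.character(genes))
  if (length(genes) == 0) stop("empty gene set")
  mean(genes %in% graph$nodes)
}

#' Write an interactome as a sorted two-column TSV
#'
#' @param graph an `interactome`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_interactome <- function(graph, path) {
  stopifnot(inherits(graph, "interactome"))
  a <- graph$nodes[graph$edges[, 1L]]
  b <- graph$nodes[graph$edges[, 2L]]
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  o <- order(lo, hi)
  utils::write.table(data.frame(from = lo[o], to = hi[o]), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Summary statistics of an interactome
#'
#' @param graph an `interactome`.
#' @return List with node count, edge count, per-source counts (if the graph
#'   came from [load_edge_lists()]) and LCC size.
#' @export
interactome_summary <- function(graph) {
  stopifnot(inherits(graph, "interactome"))
  comp <- component_labels(graph$adj)
  list(
    n_nodes = length(graph$nodes),
    n_edges = nrow(graph$edges),
    source_counts = as.list(attr(graph, "source_counts")),
    n_components = if (length(comp)) max(comp) else 0L,
    lcc_size = if (length(comp)) max(tabulate(comp)) else 0L
  )
}

# Drop genes absent from the network, warning with a count (module policy:
# analyses are restricted to the LCC, off-network genes cannot contribute
# finite distances).
on_network <- function(graph, genes, what = "gene set") {
  genes <- unique(as.character(genes))
  present <- genes[genes %in% graph$nodes]
  n_drop <- length(genes) - length(present)
  if (n_drop > 0) {
    warning(n_drop, " ", what, " member(s) absent from the network dropped")
  }
  present
}
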
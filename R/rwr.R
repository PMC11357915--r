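#' Build the heterogeneous formula-herb-ingredient-protein network
#'
#' Overlays the composition hierarchy on the protein-protein interaction
#' LCC. Node kinds are formula, herb, ingredient and protein; edge types
#' are formula-herb, herb-ingredient, ingredient-protein (only for targets
#' present in the interactome) and protein-protein (exactly the interactome
#' edges). Ingredients whose targets are all off-network are retained,
#' connected only through their herb(s), and flagged: their walk score then
#' reflects composition alone.
#'
#' @param interactome an `interactome` (expected to be an LCC).
#' @param tables a `composition_tables` object (post any drug-likeness
#'   screen).
#' @return Object of class `hetero_network`: list with `nodes` (data frame
#'   id, kind), `edges` (two-column integer matrix), `edge_type` (character
#'   vector), `flagged_ingredients` (character vector).
#' @export
build_hetero_network <- function(interactome, tables) {
  stopifnot(inherits(interactome, "interactome"),
            inherits(tables, "composition_tables"))
  fh <- tables$formula_herb
  hi <- tables$herb_ingredient
  it <- tables$ingredient_target
  if (nrow(fh) == 0 || nrow(hi) == 0) stop("empty composition tables")
  formulae <- sort(unique(fh$formula_id))
  herbs <- sort(unique(c(fh$herb_id, hi$herb_id)))
  ingredients <- sort(unique(hi$ingredient_id))
  proteins <- interactome$nodes
  nodes <- data.frame(
    id = c(formulae, herbs, ingredients, proteins),
    kind = rep(c("formula", "herb", "ingredient", "protein"),
               c(length(formulae), length(herbs), length(ingredients),
                 length(proteins))),
    stringsAsFactors = FALSE)
  key <- paste(nodes$kind, nodes$id, sep = ":")
  lookup <- stats::setNames(seq_len(nrow(nodes)), key)

  e_fh <- cbind(lookup[paste0("formula:", fh$formula_id)],
                lookup[paste0("herb:", fh$herb_id)])
  e_hi <- cbind(lookup[paste0("herb:", hi$herb_id)],
                lookup[paste0("ingredient:", hi$ingredient_id)])
  it_on <- it[it$ingredient_id %in% ingredients &
                it$gene %in% proteins, , drop = FALSE]
  e_ip <- cbind(lookup[paste0("ingredient:", it_on$ingredient_id)],
                lookup[paste0("protein:", it_on$gene)])
  e_pp <- cbind(lookup[paste0("protein:", proteins[interactome$edges[, 1L]])],
                lookup[paste0("protein:", proteins[interactome$edges[, 2L]])])
  edges <- rbind(e_fh, e_hi, e_ip, e_pp)
  edge_type <- rep(c("formula-herb", "herb-ingredient",
                     "ingredient-protein", "protein-protein"),
                   c(nrow(e_fh), nrow(e_hi), nrow(e_ip), nrow(e_pp)))
  rownames(edges) <- NULL
  storage.mode(edges) <- "integer"

  with_target <- unique(it_on$ingredient_id)
  flagged <- setdiff(ingredients, with_target)
  if (length(flagged)) {
    message(length(flagged),
            " ingredient(s) have no on-network targets (flagged)")
  }
  structure(list(nodes = nodes, edges = edges, edge_type = edge_type,
                 flagged_ingredients = flagged),
            class = "hetero_network")
}

#' @export
print.hetero_network <- function(x, ...) {
  kinds <- table(x$nodes$kind)
  types <- table(x$edge_type)
  cat("Heterogeneous network: ", nrow(x$nodes), " nodes, ",
      nrow(x$edges), " edges\n", sep = "")
  cat("  nodes: ", paste(names(kinds), kinds, sep = "=", collapse = ", "),
      "\n", sep = "")
  cat("  edges: ", paste(names(types), types, sep = "=", collapse = ", "),
      "\n", sep = "")
  if (length(x$flagged_ingredients)) {
    cat("  ingredients without on-network targets: ",
        length(x$flagged_ingredients), "\n", sep = "")
  }
  invisible(x)
}

# Column-stochastic transition operator of the flattened typed graph
# (uniform edge weight 1). Sparse, so large interactomes stay cheap.
hetero_transition_matrix <- function(network) {
  n <- nrow(network$nodes)
  e <- network$edges
  A <- Matrix::sparseMatrix(i = c(e[, 1L], e[, 2L]),
                            j = c(e[, 2L], e[, 1L]),
                            x = 1, dims = c(n, n))
  cs <- Matrix::colSums(A)
  if (any(cs == 0)) {
    # isolated nodes receive a self-loop so the operator stays stochastic
    iso <- which(cs == 0)
    A <- A + Matrix::sparseMatrix(i = iso, j = iso, x = 1, dims = c(n, n))
    cs[iso] <- 1
  }
  A %*% Matrix::Diagonal(x = 1 / cs)
}

#' Random walk with restart over the heterogeneous network
#'
#' Iterates `p <- (1 - r) * W p + r * e`, where `W` is the column-normalized
#' adjacency of the flattened typed graph and `e` is uniform over the seed
#' genes present in the network. Iteration stops when the L1 change drops
#' below `tolerance`; the steady-state scores sum to 1.
#'
#' @param network a `hetero_network`.
#' @param seeds character vector of seed gene identifiers (matched against
#'   protein nodes); seeds absent from the network are dropped with a
#'   warning, and at least one must remain.
#' @param restart restart probability in (0, 1\], default 0.7.
#' @param tolerance L1 convergence threshold, default 1e-10.
#' @param max_iterations iteration cap, default 1000.
#' @return Named numeric vector of steady-state probabilities over the
#'   composite node keys `kind:id`, with attributes `iterations` and
#'   `residual`.
#' @export
rwr <- function(network, seeds, restart = 0.7, tolerance = 1e-10,
                max_iterations = 1000) {
  stopifnot(inherits(network, "hetero_network"))
  if (!is.numeric(restart) || restart <= 0 || restart > 1) {
    stop("restart probability must lie in (0, 1]")
  }
  if (tolerance <= 0) stop("tolerance must be positive")
  seeds <- unique(as.character(seeds))
  prot <- network$nodes$kind == "protein"
  seed_idx <- which(prot & network$nodes$id %in% seeds)
  dropped <- setdiff(seeds, network$nodes$id[prot])
  if (length(dropped)) {
    warning(length(dropped), " seed(s) absent from the network dropped")
  }
  if (length(seed_idx) == 0) stop("no seed genes present in the network")
  n <- nrow(network$nodes)
  W <- hetero_transition_matrix(network)
  e <- numeric(n)
  e[seed_idx] <- 1 / length(seed_idx)
  p <- e
  iter <- 0L
  repeat {
    iter <- iter + 1L
    p_new <- as.numeric((1 - restart) * (W %*% p)) + restart * e
    delta <- sum(abs(p_new - p))
    p <- p_new
    if (delta < tolerance) break
    if (iter >= max_iterations) {
      stop("random walk did not converge after ", max_iterations,
           " iterations (L1 residual ", format(delta, digits = 3), ")")
    }
  }
  names(p) <- paste(network$nodes$kind, network$nodes$id, sep = ":")
  attr(p, "iterations") <- iter
  attr(p, "residual") <- delta
  p
}

#' Rank ingredients by random-walk score
#'
#' Restricts the steady-state scores to ingredient nodes and orders them by
#' score (descending), breaking ties by ingredient id ascending. Each
#' ingredient is annotated with the formulae containing it, derived from
#' the formula-herb and herb-ingredient edges of the network.
#'
#' @param scores named score vector from [rwr()].
#' @param network the `hetero_network` the scores were computed on.
#' @param top_fraction optional fraction in (0, 1\] to truncate the ranking
#'   (e.g. 0.01 keeps the top 1 percent).
#' @return Data frame of class `ingredient_ranking`: ingredient_id,
#'   rwr_score, rank, formulae (comma-separated), flagged (no on-network
#'   targets).
#' @export
rank_ingredients <- function(scores, network, top_fraction = NULL) {
  stopifnot(inherits(network, "hetero_network"))
  ing <- network$nodes$kind == "ingredient"
  if (!any(ing)) stop("network has no ingredient nodes")
  ids <- network$nodes$id[ing]
  sc <- unname(scores[paste0("ingredient:", ids)])
  o <- order(-sc, ids)
  membership <- ingredient_formula_map(network)
  df <- data.frame(
    ingredient_id = ids[o],
    rwr_score = sc[o],
    rank = seq_along(o),
    formulae = vapply(ids[o], function(i) {
      paste(membership[[i]], collapse = ",")
    }, "", USE.NAMES = FALSE),
    flagged = ids[o] %in% network$flagged_ingredients,
    stringsAsFactors = FALSE)
  if (!is.null(top_fraction)) {
    stopifnot(top_fraction > 0, top_fraction <= 1)
    df <- df[seq_len(max(1L, ceiling(top_fraction * nrow(df)))), ,
             drop = FALSE]
  }
  rownames(df) <- NULL
  class(df) <- c("ingredient_ranking", "data.frame")
  df
}

# formula membership per ingredient via formula-herb and herb-ingredient
# edges
ingredient_formula_map <- function(network) {
  nd <- network$nodes
  fh <- network$edges[network$edge_type == "formula-herb", , drop = FALSE]
  hi <- network$edges[network$edge_type == "herb-ingredient", , drop = FALSE]
  herb_formulae <- split(nd$id[fh[, 1L]], nd$id[fh[, 2L]])
  out <- lapply(split(nd$id[hi[, 1L]], nd$id[hi[, 2L]]), function(hs) {
    sort(unique(unlist(herb_formulae[hs], use.names = FALSE)))
  })
  out
}

#' @export
print.ingredient_ranking <- function(x, n = 10, ...) {
  cat("Ingredient ranking (", nrow(x), " ingredients)\n", sep = "")
  print.data.frame(utils::head(x, n), digits = 4)
  if (nrow(x) > n) cat("  ... ", nrow(x) - n, " more\n", sep = "")
  invisible(x)
}

#' Top-ranked ingredients per formula
#'
#' For each formula, lists its member ingredients in global rank order,
#' truncated to the top `k` (integer >= 1) or to a fraction (0 < k < 1) of
#' the formula's member list. An ingredient shared by several formulae
#' appears under each of them with its global rank.
#'
#' @param ranking an `ingredient_ranking`.
#' @param tables the `composition_tables` defining formula membership.
#' @param k_or_fraction integer count or fraction.
#' @return Named list (one element per formula) of data frames with
#'   ingredient_id, rwr_score, rank.
#' @export
per_formula_key_ingredients <- function(ranking, tables, k_or_fraction) {
  stopifnot(inherits(ranking, "ingredient_ranking"),
            inherits(tables, "composition_tables"),
            k_or_fraction > 0)
  fh <- tables$formula_herb
  hi <- tables$herb_ingredient
  ids <- unique(fh$formula_id)
  stats::setNames(lapply(ids, function(f) {
    herbs <- fh$herb_id[fh$formula_id == f]
    members <- unique(hi$ingredient_id[hi$herb_id %in% herbs])
    sub <- ranking[ranking$ingredient_id %in% members,
                   c("ingredient_id", "rwr_score", "rank"), drop = FALSE]
    k <- if (k_or_fraction >= 1) as.integer(k_or_fraction)
         else max(1L, ceiling(k_or_fraction * nrow(sub)))
    sub <- utils::head(sub, k)
    rownames(sub) <- NULL
    sub
  }), ids)
}
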
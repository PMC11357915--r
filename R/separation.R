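#' Mean within-module distance of a gene set
#'
#' Average, over the on-network members of a set, of the shortest-path
#' distance to the nearest *other* member. This is the internal term of the
#' module separation score; excluding self is what keeps it from
#' degenerating to zero.
#'
#' @param graph an `interactome`.
#' @param set_x character vector of gene identifiers; at least two must lie
#'   on the network (off-network genes are dropped with a warning).
#' @return Mean hop distance (numeric scalar).
#' @export
mean_internal_distance <- function(graph, set_x) {
  x <- on_network(graph, set_x)
  if (length(x) < 2) stop("need at least 2 on-network members")
  mean(nearest_other_member_distance(graph, x))
}

#' Mean cross-module distance between two gene sets
#'
#' Symmetric convention: the average over the nodes of *both* sets of the
#' distance to the closest node of the other set (each node counted once
#' per side). A gene shared by both sets contributes 0 on both sides, since
#' it is itself its closest node in the other set.
#'
#' @param graph an `interactome`.
#' @param set_a,set_b character vectors of gene identifiers (off-network
#'   genes dropped with a warning).
#' @return Mean hop distance (numeric scalar).
#' @export
mean_cross_distance <- function(graph, set_a, set_b) {
  a <- on_network(graph, set_a)
  b <- on_network(graph, set_b)
  if (length(a) == 0 || length(b) == 0) {
    stop("both sets need at least one on-network member")
  }
  ai <- match(a, graph$nodes)
  bi <- match(b, graph$nodes)
  d_to_b <- bfs_hops(graph$adj, bi)   # distance of every node to set B
  d_to_a <- bfs_hops(graph$adj, ai)
  vals <- c(d_to_b[ai], d_to_a[bi])
  if (anyNA(vals)) stop("sets lie in disconnected components")
  mean(vals)
}

#' Network separation score of two gene modules
#'
#' Computes the separation of two gene sets on the interactome:
#' the mean cross-module nearest-neighbour distance minus the average of
#' the two within-module nearest-neighbour distances,
#' `s_ab = <d_ab> - (<d_aa> + <d_bb>) / 2`.
#' Negative or near-zero values indicate overlapping network
#' neighbourhoods; positive values indicate topologically separated
#' modules. The score is symmetric under exchange of the two sets.
#'
#' @param graph an `interactome`.
#' @param set_a,set_b character vectors of gene identifiers, each with at
#'   least two on-network members.
#' @param id_a,id_b labels carried into the result.
#' @param d_aa optional precomputed internal distance of `set_a` (used by
#'   [separation_panel()] to avoid recomputation).
#' @return Object of class `separation_result` with fields `set_a_id`,
#'   `set_b_id`, `d_ab`, `d_aa`, `d_bb`, `s_ab`, `n_a_used`, `n_b_used`.
#' @export
separation <- function(graph, set_a, set_b, id_a = "A", id_b = "B",
                       d_aa = NULL) {
  a <- on_network(graph, set_a)
  b <- on_network(graph, set_b)
  if (length(a) < 2 || length(b) < 2) {
    stop("both sets need at least 2 on-network members")
  }
  if (is.null(d_aa)) d_aa <- mean(nearest_other_member_distance(graph, a))
  d_bb <- mean(nearest_other_member_distance(graph, b))
  d_ab <- mean_cross_distance(graph, a, b)
  structure(list(set_a_id = id_a, set_b_id = id_b,
                 d_ab = d_ab, d_aa = d_aa, d_bb = d_bb,
                 s_ab = d_ab - (d_aa + d_bb) / 2,
                 n_a_used = length(a), n_b_used = length(b)),
            class = "separation_result")
}

#' @export
print.separation_result <- function(x, ...) {
  cat("Separation ", x$set_a_id, " vs ", x$set_b_id, "\n",
      "  <d_ab> = ", format(x$d_ab, digits = 4),
      ", <d_aa> = ", format(x$d_aa, digits = 4),
      ", <d_bb> = ", format(x$d_bb, digits = 4), "\n",
      "  s_ab = ", format(x$s_ab, digits = 4),
      "   (", x$n_a_used, " and ", x$n_b_used, " genes on network)\n",
      sep = "")
  invisible(x)
}

#' Separation of a focus module against a panel of gene sets
#'
#' Computes the separation score of one focus set (e.g. a disease module)
#' against every member of a panel (e.g. syndrome gene sets), reusing the
#' focus set's internal distance, and reports the arithmetic mean score.
#' Panel members failing preconditions (fewer than two on-network genes)
#' are skipped with a warning and excluded from the mean.
#'
#' @param graph an `interactome`.
#' @param focus character vector of gene identifiers.
#' @param panel named list of character vectors.
#' @param focus_id label for the focus set.
#' @return Object of class `separation_panel`: a list with `results` (data
#'   frame: set_a, set_b, d_aa, d_bb, d_ab, s_ab, n_a_used, n_b_used) and
#'   `mean_s`.
#' @export
separation_panel <- function(graph, focus, panel, focus_id = "focus") {
  stopifnot(is.list(panel), length(panel) >= 1)
  if (is.null(names(panel))) names(panel) <- paste0("set", seq_along(panel))
  a <- on_network(graph, focus, "focus set")
  if (length(a) < 2) stop("focus set needs at least 2 on-network members")
  d_aa <- mean(nearest_other_member_distance(graph, a))
  rows <- lapply(names(panel), function(id) {
    res <- tryCatch(
      separation(graph, a, panel[[id]], id_a = focus_id, id_b = id,
                 d_aa = d_aa),
      error = function(e) {
        warning("panel member '", id, "' skipped: ", conditionMessage(e))
        NULL
      })
    if (is.null(res)) return(NULL)
    data.frame(set_a = focus_id, set_b = id, d_aa = res$d_aa,
               d_bb = res$d_bb, d_ab = res$d_ab, s_ab = res$s_ab,
               n_a_used = res$n_a_used, n_b_used = res$n_b_used,
               stringsAsFactors = FALSE)
  })
  results <- do.call(rbind, rows)
  if (is.null(results) || nrow(results) == 0) {
    stop("no panel member satisfied the separation preconditions")
  }
  structure(list(results = results, mean_s = mean(results$s_ab)),
            class = "separation_panel")
}

#' @export
print.separation_panel <- function(x, ...) {
  cat("Separation panel: ", nrow(x$results), " comparisons, mean s = ",
      format(x$mean_s, digits = 4), "\n", sep = "")
  print(x$results, digits = 4)
  invisible(x)
}
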
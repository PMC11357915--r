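#' Closest-distance proximity between a disease module and a target set
#'
#' The average, over the drug/formula targets T, of the shortest-path
#' distance to the nearest disease protein in H:
#' `d_c(H, T) = (1/|T|) * sum_{t in T} min_{h in H} d(h, t)`.
#' Computed with a single multi-source BFS from H. Note the measure is
#' directional: it averages over targets, not disease proteins.
#'
#' @param graph an `interactome`.
#' @param disease character vector of disease/syndrome gene identifiers (H).
#' @param targets character vector of drug/formula target identifiers (T).
#' @return Mean hop distance (numeric scalar); 0 iff all on-network targets
#'   are disease proteins.
#' @export
closest_distance <- function(graph, disease, targets) {
  h <- on_network(graph, disease, "disease set")
  t <- on_network(graph, targets, "target set")
  if (length(h) == 0 || length(t) == 0) {
    stop("both sets need at least one on-network member")
  }
  d <- bfs_hops(graph$adj, match(h, graph$nodes))[match(t, graph$nodes)]
  if (anyNA(d)) stop("target(s) unreachable from the disease set")
  mean(d)
}

#' Build log-scaled degree bins for degree-preserving sampling
#'
#' Partitions all nodes into log2 degree bins. Bins holding fewer than
#' `min_bin_size` nodes are merged with the next higher bin; a deficient
#' highest bin is merged downward. Exact-degree matching is impossible for
#' hubs in a finite network, so the permutation null samples within these
#' bins instead.
#'
#' @param graph an `interactome`.
#' @param min_bin_size minimum nodes per bin (default 100).
#' @return Object of class `degree_bins`: list with `bins` (list of integer
#'   node-index vectors) and `bin_of` (integer vector over nodes).
#' @export
build_degree_bins <- function(graph, min_bin_size = 100) {
  stopifnot(inherits(graph, "interactome"))
  n <- length(graph$nodes)
  if (min_bin_size < 1) stop("min_bin_size must be >= 1")
  if (min_bin_size > n) stop("min_bin_size exceeds the number of nodes")
  deg <- lengths(graph$adj)
  key <- ifelse(deg > 0, floor(log2(deg)), -1L)
  keys <- sort(unique(key))
  bins <- lapply(keys, function(k) which(key == k))
  # merge low-occupancy bins upward, then a deficient top bin downward
  i <- 1L
  while (i < length(bins)) {
    if (length(bins[[i]]) < min_bin_size) {
      bins[[i + 1L]] <- c(bins[[i]], bins[[i + 1L]])
      bins[[i]] <- NULL
    } else {
      i <- i + 1L
    }
  }
  if (length(bins) > 1L &&
      length(bins[[length(bins)]]) < min_bin_size) {
    k <- length(bins)
    bins[[k - 1L]] <- c(bins[[k - 1L]], bins[[k]])
    bins[[k]] <- NULL
  }
  bins <- lapply(bins, function(v) sort(as.integer(v)))
  bin_of <- integer(n)
  for (b in seq_along(bins)) bin_of[bins[[b]]] <- b
  structure(list(bins = bins, bin_of = bin_of), class = "degree_bins")
}

#' @export
print.degree_bins <- function(x, ...) {
  cat("Degree bins: ", length(x$bins), " bin(s) of sizes ",
      paste(lengths(x$bins), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Draw a degree-matched random node set
#'
#' Samples, without replacement, a node set of the same size and the same
#' per-bin degree histogram as a reference set. Repeated draws preserve the
#' reference's bin histogram exactly.
#'
#' @param graph an `interactome`.
#' @param bins a `degree_bins` object for the same graph.
#' @param reference character vector of node identifiers on the network.
#' @return Character vector of sampled node identifiers.
#' @export
degree_matched_sample <- function(graph, bins, reference) {
  stopifnot(inherits(graph, "interactome"), inherits(bins, "degree_bins"))
  idx <- match(unique(as.character(reference)), graph$nodes)
  if (anyNA(idx)) stop("reference node(s) not in graph")
  demand <- tabulate(bins$bin_of[idx], nbins = length(bins$bins))
  picks <- integer(0)
  for (b in which(demand > 0L)) {
    pool <- bins$bins[[b]]
    if (demand[b] > length(pool)) {
      stop("bin ", b, " holds ", length(pool), " nodes but ", demand[b],
           " are required")
    }
    picks <- c(picks, pool[sample.int(length(pool), demand[b])])
  }
  graph$nodes[picks]
}

#' Proximity with a degree-preserving permutation null
#'
#' Computes the observed closest-distance proximity `d_c(H, T)` and builds
#' its null by jointly resampling *both* the disease set and the target set
#' degree-matched from the whole network, `n_perm` times. The z-score is
#' `(d_obs - mean(d_null)) / sd(d_null)` and the one-sided empirical
#' P-value is add-one smoothed: `(#{d_null <= d_obs} + 1) / (n_perm + 1)`.
#' A pair is flagged significant by the dual criterion z < -1.5 and
#' P < 0.05.
#'
#' @param graph an `interactome` (typically an LCC).
#' @param disease character vector of disease/syndrome genes (H).
#' @param targets character vector of drug/formula targets (T), or a
#'   `target_profile`.
#' @param n_perm number of paired permutations (default 100).
#' @param bins optional precomputed `degree_bins`; built with
#'   `min_bin_size` otherwise.
#' @param min_bin_size passed to [build_degree_bins()] (default 100).
#' @param disease_id,entity_id labels carried into the result.
#' @return Object of class `proximity_result` with fields `disease_id`,
#'   `entity_id`, `d_obs`, `null_mean`, `null_sd`, `z`, `p_empirical`,
#'   `n_perm`, `significant`, `degenerate_null`.
#' @export
proximity <- function(graph, disease, targets, n_perm = 100, bins = NULL,
                      min_bin_size = 100, disease_id = "disease",
                      entity_id = "entity") {
  if (inherits(targets, "target_profile")) {
    entity_id <- targets$entity_id
    targets <- targets$targets
  }
  if (n_perm < 2) stop("n_perm must be at least 2")
  h <- on_network(graph, disease, "disease set")
  t <- on_network(graph, targets, "target set")
  if (length(h) == 0 || length(t) == 0) {
    stop("both sets need at least one on-network member")
  }
  if (is.null(bins)) bins <- build_degree_bins(graph, min_bin_size)
  hi <- match(h, graph$nodes)
  ti <- match(t, graph$nodes)
  d_obs <- mean(bfs_hops(graph$adj, hi)[ti])
  d_null <- vapply(seq_len(n_perm), function(k) {
    h_perm <- match(degree_matched_sample(graph, bins, h), graph$nodes)
    t_perm <- match(degree_matched_sample(graph, bins, t), graph$nodes)
    mean(bfs_hops(graph$adj, h_perm)[t_perm])
  }, numeric(1))
  null_mean <- mean(d_null)
  null_sd <- stats::sd(d_null)
  degenerate <- !is.finite(null_sd) || null_sd == 0
  z <- if (degenerate) NA_real_ else (d_obs - null_mean) / null_sd
  p <- (sum(d_null <= d_obs) + 1) / (n_perm + 1)
  significant <- !degenerate && z < -1.5 && p < 0.05
  structure(list(disease_id = disease_id, entity_id = entity_id,
                 d_obs = d_obs, null_mean = null_mean, null_sd = null_sd,
                 z = z, p_empirical = p, n_perm = n_perm,
                 significant = significant, degenerate_null = degenerate),
            class = "proximity_result")
}

#' @export
print.proximity_result <- function(x, ...) {
  cat("Proximity ", x$entity_id, " -> ", x$disease_id, "\n",
      "  d_obs = ", format(x$d_obs, digits = 4),
      "  null ", format(x$null_mean, digits = 4), " +/- ",
      format(x$null_sd, digits = 4), " (", x$n_perm, " permutations)\n",
      "  z = ", format(x$z, digits = 4), ", P = ",
      format(x$p_empirical, digits = 4),
      if (isTRUE(x$significant)) "  [significant: z < -1.5, P < 0.05]"
      else "", "\n", sep = "")
  if (isTRUE(x$degenerate_null)) {
    cat("  note: degenerate null (sd = 0); z undefined\n")
  }
  invisible(x)
}

#' Proximity matrix over disease and entity panels
#'
#' One proximity permutation test per (disease, entity) pair. Each cell
#' draws its permutations from an RNG stream derived from the pair's
#' labels and a base seed, so results are deterministic given the seed and
#' reordering the entity list permutes rows without changing any value.
#'
#' @param graph an `interactome`.
#' @param diseases named list of character vectors.
#' @param entities named list of character vectors or `target_profile`s;
#'   unusable profiles are skipped with a warning.
#' @param n_perm permutations per pair (default 100).
#' @param min_bin_size passed to [build_degree_bins()].
#' @param seed base seed for the per-pair RNG streams; drawn from the
#'   session RNG when `NULL`.
#' @return Data frame (class `proximity_matrix`) with one row per pair:
#'   disease_id, entity_id, d_obs, null_mean, null_sd, z, p_empirical,
#'   n_perm, significant.
#' @export
proximity_matrix <- function(graph, diseases, entities, n_perm = 100,
                             min_bin_size = 100, seed = NULL) {
  stopifnot(is.list(diseases), length(diseases) >= 1,
            is.list(entities), length(entities) >= 1)
  if (is.null(names(diseases))) {
    names(diseases) <- paste0("disease", seq_along(diseases))
  }
  if (is.null(names(entities))) {
    names(entities) <- paste0("entity", seq_along(entities))
  }
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1)
  bins <- build_degree_bins(graph, min_bin_size)
  rows <- list()
  for (d_id in names(diseases)) {
    for (e_id in names(entities)) {
      ent <- entities[[e_id]]
      if (inherits(ent, "target_profile")) {
        if (!ent$usable) {
          warning("entity '", e_id, "' unusable; skipped")
          next
        }
        ent <- ent$targets
      }
      res <- with_stream_seed(stable_seed(seed, d_id, e_id), {
        proximity(graph, diseases[[d_id]], ent, n_perm = n_perm,
                  bins = bins, disease_id = d_id, entity_id = e_id)
      })
      rows[[length(rows) + 1L]] <- data.frame(
        disease_id = d_id, entity_id = e_id, d_obs = res$d_obs,
        null_mean = res$null_mean, null_sd = res$null_sd, z = res$z,
        p_empirical = res$p_empirical, n_perm = res$n_perm,
        significant = res$significant, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("proximity_matrix", "data.frame")
  out
}

# Deterministic 31-bit seed from a base seed and a list of strings
# (polynomial rolling hash mod a Mersenne prime).
stable_seed <- function(seed, ...) {
  m <- 2147483647
  h <- as.numeric(seed) %% m
  for (s in c(...)) {
    for (byte in utf8ToInt(s)) h <- (h * 131 + byte) %% m
  }
  as.integer(h)
}

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards.
with_stream_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
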
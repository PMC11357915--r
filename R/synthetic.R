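#' Generate a scale-free synthetic interactome
#'
#' Preferential-attachment construction: a seed clique on `attachment + 1`
#' nodes, then each new node attaches to `attachment` distinct existing
#' nodes with probability proportional to their current degree. The graph
#' is therefore connected by construction with exactly
#' `attachment * (attachment + 1) / 2 + attachment * (n_nodes - attachment - 1)`
#' edges, and its degree distribution is heavy-tailed. Uses the session
#' RNG; call `set.seed()` for reproducibility.
#'
#' @param n_nodes number of nodes (>= 10).
#' @param attachment edges added per new node (default 2).
#' @return An `interactome` with node labels `g00001`, `g00002`, ...
#' @export
generate_interactome <- function(n_nodes, attachment = 2) {
  if (n_nodes < 10) stop("n_nodes must be at least 10")
  m <- as.integer(attachment)
  stopifnot(m >= 1, m + 1 <= n_nodes)
  deg <- integer(n_nodes)
  seedN <- m + 1L
  seed_pairs <- utils::combn(seedN, 2L)
  from <- seed_pairs[1L, ]
  to <- seed_pairs[2L, ]
  deg[seq_len(seedN)] <- m
  # grow; sample targets without replacement, weight = current degree
  from_rest <- integer(m * (n_nodes - seedN))
  to_rest <- integer(m * (n_nodes - seedN))
  pos <- 0L
  for (v in seq.int(seedN + 1L, n_nodes)) {
    existing <- seq_len(v - 1L)
    targets <- existing[sample.int(v - 1L, m, prob = deg[existing])]
    from_rest[pos + seq_len(m)] <- v
    to_rest[pos + seq_len(m)] <- targets
    pos <- pos + m
    deg[targets] <- deg[targets] + 1L
    deg[v] <- m
  }
  lab <- sprintf("g%05d", c(from, from_rest))
  lab2 <- sprintf("g%05d", c(to, to_rest))
  as_interactome(lab, lab2)
}

#' Plant a cohesive gene module in a graph
#'
#' Grows a connected node set by seeded BFS with random frontier
#' selection. At each step, with probability `cohesiveness` the frontier
#' node with the most edges into the current module is taken (random tie
#' break), otherwise a uniform frontier node. Higher cohesiveness yields
#' modules with smaller mean internal distance, emulating the assumption
#' that disease- and syndrome-related proteins cluster in closely
#' connected subnetworks.
#'
#' @param graph an `interactome`.
#' @param size module size (<= number of nodes).
#' @param cohesiveness in \[0, 1\], default 0.8.
#' @return Character vector of module node identifiers.
#' @export
plant_module <- function(graph, size, cohesiveness = 0.8) {
  stopifnot(inherits(graph, "interactome"))
  n <- length(graph$nodes)
  if (size > n) stop("module size exceeds the number of nodes")
  start <- sample.int(n, 1L)
  idx <- grow_module(graph$adj, start, size, cohesiveness,
                     forbidden = integer(0))
  graph$nodes[idx]
}

# seeded-BFS growth with cohesiveness-controlled frontier selection
grow_module <- function(adj, seed_idx, size, cohesiveness, forbidden) {
  n <- length(adj)
  in_mod <- rep(FALSE, n)
  blocked <- rep(FALSE, n)
  blocked[forbidden] <- TRUE
  mod <- as.integer(seed_idx)
  in_mod[mod] <- TRUE
  # edges into module per node, maintained incrementally
  cnt <- integer(n)
  for (v in mod) cnt[adj[[v]]] <- cnt[adj[[v]]] + 1L
  while (length(mod) < size) {
    frontier <- which(cnt > 0L & !in_mod & !blocked)
    if (length(frontier) == 0L) {
      stop("module growth exhausted the reachable region at size ",
           length(mod), " (requested ", size, ")")
    }
    if (stats::runif(1) < cohesiveness) {
      best <- frontier[cnt[frontier] == max(cnt[frontier])]
      pick <- best[sample.int(length(best), 1L)]
    } else {
      pick <- frontier[sample.int(length(frontier), 1L)]
    }
    mod <- c(mod, pick)
    in_mod[pick] <- TRUE
    cnt[adj[[pick]]] <- cnt[adj[[pick]]] + 1L
  }
  mod
}

#' Plant a module with controlled overlap against a base module
#'
#' Returns a module of the requested size sharing exactly `n_shared` genes
#' with `base`: a random shared core is drawn from `base` and the
#' remainder is grown adjacent to that core while avoiding the rest of
#' `base`. With `n_shared = 0` the module is grown disjoint from `base`.
#'
#' @param graph an `interactome`.
#' @param base character vector (the base module).
#' @param size size of the new module.
#' @param n_shared exact overlap with `base` (<= min(size, |base|)).
#' @param cohesiveness growth parameter as in [plant_module()].
#' @return Character vector of module node identifiers.
#' @export
plant_overlapping_module <- function(graph, base, size, n_shared,
                                     cohesiveness = 0.8) {
  stopifnot(inherits(graph, "interactome"))
  base_idx <- match(unique(as.character(base)), graph$nodes)
  if (anyNA(base_idx)) stop("base module node(s) not in graph")
  if (n_shared > min(size, length(base_idx))) {
    stop("requested overlap exceeds min(size, |base|)")
  }
  if (n_shared == size) {
    shared <- base_idx[sample.int(length(base_idx), n_shared)]
    return(graph$nodes[shared])
  }
  # growth can be boxed in by the forbidden region around an unlucky
  # seed; retry with fresh random seeds before declaring infeasibility
  idx <- NULL
  last_err <- NULL
  for (attempt in 1:50) {
    idx <- tryCatch({
      if (n_shared > 0) {
        shared <- base_idx[sample.int(length(base_idx), n_shared)]
        forbidden <- setdiff(base_idx, shared)
        grow_module(graph$adj, shared, size, cohesiveness, forbidden)
      } else {
        pool <- setdiff(seq_along(graph$nodes), base_idx)
        if (length(pool) == 0) stop("no nodes outside the base module")
        start <- pool[sample.int(length(pool), 1L)]
        grow_module(graph$adj, start, size, cohesiveness, base_idx)
      }
    }, error = function(e) {
      last_err <<- e
      NULL
    })
    if (!is.null(idx)) break
  }
  if (is.null(idx)) {
    stop("infeasible overlap request: ", conditionMessage(last_err))
  }
  graph$nodes[idx]
}

#' Plant a target profile at a controlled distance from a module
#'
#' Draws targets uniformly from the stratum of nodes whose hop distance to
#' the module equals `placement_distance`, emulating the assumption that
#' effective drugs target proteins near the disease module (placement 0:
#' targets inside the module; placement 1: observed closest-distance
#' proximity exactly 1).
#'
#' @param graph an `interactome`.
#' @param module character vector of module node identifiers.
#' @param n_targets number of targets to draw.
#' @param placement_distance required hop distance (>= 0).
#' @param entity_id label for the profile.
#' @return A `target_profile` (entity_kind `"drug"`).
#' @export
plant_target_profile <- function(graph, module, n_targets,
                                 placement_distance,
                                 entity_id = paste0("planted_d",
                                                    placement_distance)) {
  stopifnot(placement_distance >= 0, n_targets >= 1)
  d <- nearest_set_distance(graph, module)
  stratum <- names(d)[d == placement_distance]
  if (length(stratum) < n_targets) {
    avail <- table(d[is.finite(d)])
    stop("only ", length(stratum), " node(s) at distance ",
         placement_distance, " (need ", n_targets, "); available strata: ",
         paste(names(avail), avail, sep = ":", collapse = ", "))
  }
  targets <- stratum[sample.int(length(stratum), n_targets)]
  structure(list(entity_id = entity_id, entity_kind = "drug",
                 targets = sort(targets), provenance = NULL, usable = TRUE),
            class = "target_profile")
}

#' Generate a formula hierarchy fixture with planted active ingredients
#'
#' Builds composition tables for one formula per supplied module. Each
#' formula receives one planted "active" ingredient whose targets all lie
#' inside its module, plus `decoys_per_formula` decoy ingredients with
#' targets drawn uniformly from the whole graph. Drug-likeness scores are
#' assigned so actives score high and decoys low, letting a screening
#' threshold separate them exactly.
#'
#' @param graph an `interactome`.
#' @param modules named list of character vectors (one module per
#'   formula; names become formula ids).
#' @param n_herbs herbs per formula (default 2).
#' @param decoys_per_formula decoy ingredients per formula (default 20).
#' @param targets_per_ingredient targets per ingredient (default 8).
#' @param active_score_range,decoy_score_range uniform ranges for the
#'   drug-likeness scores (defaults keep every decoy below 0.3 and every
#'   active above it).
#' @return List with `tables` (a `composition_tables`) and `ground_truth`
#'   (named character vector: formula id -> active ingredient id).
#' @export
generate_formula_fixture <- function(graph, modules, n_herbs = 2,
                                     decoys_per_formula = 20,
                                     targets_per_ingredient = 8,
                                     active_score_range = c(0.6, 0.95),
                                     decoy_score_range = c(0.05, 0.25)) {
  stopifnot(inherits(graph, "interactome"), is.list(modules),
            length(modules) >= 1)
  if (is.null(names(modules))) {
    names(modules) <- paste0("F", seq_along(modules))
  }
  n <- length(graph$nodes)
  fh <- list(); hi <- list(); it <- list()
  scores <- numeric(0)
  truth <- character(0)
  for (i in seq_along(modules)) {
    f_id <- names(modules)[i]
    module <- as.character(modules[[i]])
    herbs <- sprintf("%s_H%02d", f_id, seq_len(n_herbs))
    fh[[i]] <- data.frame(formula_id = f_id, herb_id = herbs,
                          stringsAsFactors = FALSE)
    act_id <- sprintf("%s_ACT", f_id)
    truth[f_id] <- act_id
    k_act <- min(targets_per_ingredient, length(module))
    act_targets <- module[sample.int(length(module), k_act)]
    dec_ids <- sprintf("%s_DEC%02d", f_id, seq_len(decoys_per_formula))
    ing_ids <- c(act_id, dec_ids)
    hi[[i]] <- data.frame(
      herb_id = herbs[1L + (seq_along(ing_ids) - 1L) %% n_herbs],
      ingredient_id = ing_ids, stringsAsFactors = FALSE)
    dec_targets <- lapply(dec_ids, function(.) {
      graph$nodes[sample.int(n, targets_per_ingredient)]
    })
    it[[i]] <- data.frame(
      ingredient_id = rep(ing_ids, c(k_act,
                                     rep(targets_per_ingredient,
                                         decoys_per_formula))),
      gene = c(act_targets, unlist(dec_targets)),
      stringsAsFactors = FALSE)
    scores[act_id] <- stats::runif(1, active_score_range[1],
                                   active_score_range[2])
    scores[dec_ids] <- stats::runif(decoys_per_formula,
                                    decoy_score_range[1],
                                    decoy_score_range[2])
  }
  tables <- composition_tables(do.call(rbind, fh), do.call(rbind, hi),
                               do.call(rbind, it), scores)
  list(tables = tables, ground_truth = truth)
}

#' Write a complete synthetic input bundle to a directory
#'
#' Generates an interactome, a disease module, overlapping syndrome
#' modules, disjoint control modules and a formula hierarchy with planted
#' actives, and writes them in the package's input formats (edge-list TSV,
#' GMT gene sets, composition TSVs, drug-likeness TSV, ground-truth JSON).
#' Defaults reflect the synthetic study conditions used throughout the
#' package's validation suite.
#'
#' @param dir output directory (created if missing).
#' @param n_nodes,attachment interactome size and attachment parameter.
#' @param disease_size disease module size (default 40).
#' @param n_syndromes number of related syndrome modules (default 5).
#' @param syndrome_size syndrome module size (default 35).
#' @param syndrome_overlap genes shared between each syndrome and the
#'   disease module (default 12).
#' @param n_controls number of disjoint control modules (default 20).
#' @param control_size control module size (default 35).
#' @param decoys_per_formula decoys per formula (default 20).
#' @return Invisibly, a named list of the written file paths plus the
#'   ground-truth record.
#' @export
simulate_study_inputs <- function(dir, n_nodes = 600, attachment = 2,
                                  disease_size = 40, n_syndromes = 5,
                                  syndrome_size = 35, syndrome_overlap = 12,
                                  n_controls = 20, control_size = 35,
                                  decoys_per_formula = 20) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  g <- generate_interactome(n_nodes, attachment)
  disease <- plant_module(g, disease_size)
  syndromes <- stats::setNames(lapply(seq_len(n_syndromes), function(i) {
    plant_overlapping_module(g, disease, syndrome_size, syndrome_overlap)
  }), sprintf("S%d", seq_len(n_syndromes)))
  controls <- stats::setNames(lapply(seq_len(n_controls), function(i) {
    plant_overlapping_module(g, disease, control_size, 0)
  }), sprintf("C%02d", seq_len(n_controls)))
  # formula Fi is planted to act on syndrome Si
  fix <- generate_formula_fixture(
    g, stats::setNames(syndromes, sprintf("F%d", seq_len(n_syndromes))),
    decoys_per_formula = decoys_per_formula)
  paths <- list(
    network = file.path(dir, "network.tsv"),
    disease = file.path(dir, "disease.gmt"),
    syndromes = file.path(dir, "syndromes.gmt"),
    controls = file.path(dir, "controls.gmt"),
    formula_herb = file.path(dir, "formula_herb.tsv"),
    herb_ingredient = file.path(dir, "herb_ingredient.tsv"),
    ingredient_target = file.path(dir, "ingredient_target.tsv"),
    druglikeness = file.path(dir, "druglikeness.tsv"),
    ground_truth = file.path(dir, "ground_truth.json"))
  write_interactome(g, paths$network)
  write_gene_sets(list(disease = disease), paths$disease)
  write_gene_sets(syndromes, paths$syndromes)
  write_gene_sets(controls, paths$controls)
  wt <- function(df, p) utils::write.table(df, p, sep = "\t", quote = FALSE,
                                           row.names = FALSE)
  wt(fix$tables$formula_herb, paths$formula_herb)
  wt(fix$tables$herb_ingredient, paths$herb_ingredient)
  wt(fix$tables$ingredient_target, paths$ingredient_target)
  wt(data.frame(ingredient_id = names(fix$tables$druglikeness),
                score = unname(fix$tables$druglikeness)),
     paths$druglikeness)
  jsonlite::write_json(list(active_by_formula = as.list(fix$ground_truth)),
                       paths$ground_truth, auto_unbox = TRUE)
  invisible(c(paths, list(ground_truth_record = fix$ground_truth)))
}
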
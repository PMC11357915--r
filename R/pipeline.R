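#' Run the full network-medicine pipeline from one configuration
#'
#' Orchestrates the three result stages — module separation panel,
#' proximity matrices and random-walk ingredient ranking, plus optional
#' enrichment comparison — from a single configuration, writing each
#' stage's artifacts and a machine-readable run manifest into an output
#' directory. One global seed fans out to per-stage child seeds by stable
#' hashing of the stage names, so re-running a stage reproduces it without
#' cross-stage RNG coupling.
#'
#' The configuration is a list (or a YAML/JSON file path) with elements:
#' \describe{
#'   \item{network}{path(s) to edge-list TSVs (required).}
#'   \item{mapping}{optional identifier-mapping TSV (source, canonical).}
#'   \item{focus}{GMT path of the focus (disease) gene set(s); the first
#'     set is the focus module.}
#'   \item{panel}{GMT path of the comparison panel (e.g. syndromes).}
#'   \item{composition}{optional list with `formula_herb`,
#'     `herb_ingredient`, `ingredient_target`, and optionally
#'     `druglikeness` paths; when absent the proximity-to-formula and RWR
#'     stages are skipped with a notice.}
#'   \item{annotation}{optional pathway GMT for enrichment.}
#'   \item{class_map}{optional TSV (pathway_id, class_label).}
#'   \item{seeds}{optional GMT whose union seeds the random walk; defaults
#'     to the panel sets.}
#'   \item{params}{optional list: `n_perm` (default 100), `restart`
#'     (default 0.7), `druglikeness_threshold` (default 0),
#'     `min_bin_size` (default 100), `top_k` (default 5), `seed`
#'     (default 1).}
#' }
#'
#' @param config configuration list or path to a YAML/JSON config file.
#' @param out_dir output directory (created if missing).
#' @return Invisibly, a list with the stage artifact paths and key results
#'   (`separation`, `proximity`, `ranking`, `manifest`).
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1) {
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
              else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config), !is.null(config$network))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  p <- config$params
  n_perm <- p$n_perm %||% 100
  restart <- p$restart %||% 0.7
  dl_thr <- p$druglikeness_threshold %||% 0
  min_bin <- p$min_bin_size %||% 100
  top_k <- p$top_k %||% 5
  seed <- p$seed %||% 1
  artifacts <- list()
  run_stage <- function(name, fun) {
    set.seed(stable_seed(seed, "stage", name))
    tryCatch(fun(), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # --- stage: network ------------------------------------------------
  net <- run_stage("network", function() {
    g <- load_edge_lists(config$network)
    if (!is.null(config$mapping)) {
      map <- utils::read.delim(config$mapping, header = FALSE,
                               colClasses = "character")
      g <- apply_mapping(g, map)
    }
    lcc <- extract_lcc(g)
    path_net <- file.path(out_dir, "network_lcc.tsv")
    write_interactome(lcc, path_net)
    summ <- interactome_summary(g)
    summ$lcc_nodes <- length(lcc$nodes)
    summ$lcc_edges <- nrow(lcc$edges)
    path_sum <- file.path(out_dir, "network_summary.json")
    jsonlite::write_json(summ, path_sum, auto_unbox = TRUE, pretty = TRUE)
    artifacts[["network"]] <<- c(path_net, path_sum)
    lcc
  })

  # --- stage: separation ---------------------------------------------
  sep <- NULL
  if (!is.null(config$focus) && !is.null(config$panel)) {
    sep <- run_stage("separation", function() {
      focus_sets <- read_gene_sets(config$focus)
      panel <- read_gene_sets(config$panel)
      res <- separation_panel(net, focus_sets[[1L]], panel,
                              focus_id = names(focus_sets)[1L])
      path_tsv <- file.path(out_dir, "separation.tsv")
      utils::write.table(format_num(res$results), path_tsv, sep = "\t",
                         quote = FALSE, row.names = FALSE)
      path_json <- file.path(out_dir, "separation_summary.json")
      jsonlite::write_json(list(focus = names(focus_sets)[1L],
                                n_panel = nrow(res$results),
                                mean_s = res$mean_s),
                           path_json, auto_unbox = TRUE, digits = NA)
      artifacts[["separation"]] <<- c(path_tsv, path_json)
      res
    })
  }

  # --- stages needing composition tables -----------------------------
  prox <- ranking <- NULL
  if (!is.null(config$composition)) {
    comp <- run_stage("composition", function() {
      tb <- read_composition(config$composition$formula_herb,
                             config$composition$herb_ingredient,
                             config$composition$ingredient_target,
                             config$composition$druglikeness)
      if (dl_thr > 0) tb <- filter_druglike(tb, dl_thr) else tb
    })
    prox <- run_stage("proximity", function() {
      focus_sets <- if (!is.null(config$focus)) read_gene_sets(config$focus)
                    else list()
      panel <- if (!is.null(config$panel)) read_gene_sets(config$panel)
               else list()
      diseases <- c(focus_sets, panel)
      profiles <- assemble_all_formula_targets(comp)
      res <- proximity_matrix(net, diseases, profiles, n_perm = n_perm,
                              min_bin_size = min_bin,
                              seed = stable_seed(seed, "stage", "proximity"))
      path_tsv <- file.path(out_dir, "proximity.tsv")
      utils::write.table(format_num(res), path_tsv, sep = "\t",
                         quote = FALSE, row.names = FALSE)
      path_json <- file.path(out_dir, "proximity_matrix.json")
      d_lv <- unique(res$disease_id)
      e_lv <- unique(res$entity_id)
      zm <- matrix(NA_real_, length(d_lv), length(e_lv),
                   dimnames = list(d_lv, e_lv))
      zm[cbind(res$disease_id, res$entity_id)] <- res$z
      jsonlite::write_json(
        list(diseases = d_lv, entities = e_lv,
             z = stats::setNames(
               lapply(seq_along(d_lv), function(i) as.list(zm[i, ])),
               d_lv)),
        path_json, auto_unbox = TRUE, digits = NA)
      artifacts[["proximity"]] <<- c(path_tsv, path_json)
      res
    })
    ranking <- run_stage("rwr", function() {
      seeds <- if (!is.null(config$seeds)) {
        unique(unlist(read_gene_sets(config$seeds), use.names = FALSE))
      } else if (!is.null(config$panel)) {
        unique(unlist(read_gene_sets(config$panel), use.names = FALSE))
      } else stop("no seed gene sets configured")
      hn <- build_hetero_network(net, comp)
      scores <- rwr(hn, seeds, restart = restart)
      rk <- rank_ingredients(scores, hn)
      path_rank <- file.path(out_dir, "ingredient_ranking.tsv")
      utils::write.table(format_num(as.data.frame(rk)), path_rank,
                         sep = "\t", quote = FALSE, row.names = FALSE)
      per_f <- per_formula_key_ingredients(rk, comp, top_k)
      path_key <- file.path(out_dir, "key_ingredients.tsv")
      key_df <- do.call(rbind, lapply(names(per_f), function(f) {
        cbind(formula_id = f, per_f[[f]])
      }))
      utils::write.table(format_num(key_df), path_key, sep = "\t",
                         quote = FALSE, row.names = FALSE)
      # node/edge export for external visualization
      path_nodes <- file.path(out_dir, "hetero_nodes.tsv")
      path_edges <- file.path(out_dir, "hetero_edges.tsv")
      utils::write.table(hn$nodes, path_nodes, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      ed <- data.frame(from = hn$nodes$id[hn$edges[, 1L]],
                       to = hn$nodes$id[hn$edges[, 2L]],
                       type = hn$edge_type, stringsAsFactors = FALSE)
      utils::write.table(ed, path_edges, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      artifacts[["rwr"]] <<- c(path_rank, path_key, path_nodes, path_edges)
      rk
    })
  } else {
    message("no composition tables configured; proximity-to-formula and ",
            "RWR stages skipped")
  }

  # --- stage: enrichment ---------------------------------------------
  enrich <- NULL
  if (!is.null(config$annotation) && !is.null(config$focus) &&
      !is.null(config$panel)) {
    enrich <- run_stage("enrichment", function() {
      anno <- read_gene_sets(config$annotation)
      class_map <- if (!is.null(config$class_map)) {
        utils::read.delim(config$class_map, header = TRUE,
                          colClasses = "character")
      } else NULL
      entities <- c(read_gene_sets(config$focus),
                    read_gene_sets(config$panel))
      rows <- lapply(entities, function(gs) {
        hypergeometric_ora(gs, anno, net$nodes)
      })
      cmpr <- compare_profiles(rows, class_map)
      path_long <- file.path(out_dir, "enrichment_comparison.tsv")
      utils::write.table(format_num(cmpr$pathways), path_long, sep = "\t",
                         quote = FALSE, row.names = FALSE)
      artifacts[["enrichment"]] <<- path_long
      cmpr
    })
  }

  # --- manifest ------------------------------------------------------
  manifest_path <- file.path(out_dir, "manifest.json")
  inputs <- unlist(config[c("network", "mapping", "focus", "panel",
                            "annotation", "class_map", "seeds")],
                   use.names = FALSE)
  inputs <- c(inputs, unlist(config$composition, use.names = FALSE))
  inputs <- inputs[!is.na(inputs) & file.exists(inputs)]
  outputs <- unlist(artifacts, use.names = FALSE)
  manifest <- list(
    package = "tcmnet",
    version = as.character(utils::packageVersion("tcmnet")),
    parameters = list(n_perm = n_perm, restart = restart,
                      druglikeness_threshold = dl_thr,
                      min_bin_size = min_bin, top_k = top_k, seed = seed),
    stage_seeds = stats::setNames(
      lapply(c("network", "separation", "composition", "proximity", "rwr",
               "enrichment"), function(s) stable_seed(seed, "stage", s)),
      c("network", "separation", "composition", "proximity", "rwr",
        "enrichment")),
    input_checksums = as.list(tools::md5sum(inputs)),
    output_checksums = as.list(tools::md5sum(outputs)))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(list(network = net, separation = sep, proximity = prox,
                 ranking = ranking, enrichment = enrich,
                 artifacts = artifacts, manifest = manifest_path))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# fixed-precision numeric formatting for TSV outputs (6 significant digits)
format_num <- function(df) {
  num <- vapply(df, is.numeric, TRUE) & !vapply(df, is.integer, TRUE)
  df[num] <- lapply(df[num], function(x) signif(x, 6))
  df
}
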
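#' Hypergeometric over-representation analysis
#'
#' Tests each pathway for over-representation in a query gene set against a
#' background universe, using the exact upper-tail hypergeometric
#' probability P(X >= overlap), with Benjamini-Hochberg adjustment across
#' the tested pathways. Pathways with no member in the universe are
#' dropped. Rows are flagged significant when p_raw < `p_cutoff` and
#' p_adjusted < `padj_cutoff`.
#'
#' @param query character vector of genes; its intersection with the
#'   universe must be non-empty.
#' @param annotation named list of character vectors (pathway members).
#' @param universe background gene set (e.g. the interactome node set).
#' @param p_cutoff raw P-value cutoff for the significance flag (default
#'   0.05).
#' @param padj_cutoff adjusted P-value cutoff (default 0.2).
#' @return Data frame of class `enrichment_result`, sorted by p_adjusted
#'   then p_raw: pathway_id, overlap, query_size, pathway_size,
#'   universe_size, gene_ratio, p_raw, p_adjusted, significant.
#' @export
hypergeometric_ora <- function(query, annotation, universe,
                               p_cutoff = 0.05, padj_cutoff = 0.2) {
  stopifnot(is.list(annotation), !is.null(names(annotation)))
  universe <- unique(as.character(universe))
  q <- intersect(unique(as.character(query)), universe)
  if (length(q) == 0) stop("query has no genes in the universe")
  N <- length(universe)
  k <- length(q)
  rows <- lapply(names(annotation), function(pid) {
    pw <- intersect(unique(annotation[[pid]]), universe)
    m <- length(pw)
    if (m == 0) return(NULL)
    x <- length(intersect(q, pw))
    p <- stats::phyper(x - 1, m, N - m, k, lower.tail = FALSE)
    data.frame(pathway_id = pid, overlap = x, query_size = k,
               pathway_size = m, universe_size = N,
               gene_ratio = x / k, p_raw = p, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0) stop("no pathway has members in the universe")
  df <- do.call(rbind, rows)
  df$p_adjusted <- stats::p.adjust(df$p_raw, method = "BH")
  df$significant <- df$p_raw < p_cutoff & df$p_adjusted < padj_cutoff
  df <- df[order(df$p_adjusted, df$p_raw, df$pathway_id), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("enrichment_result", "data.frame")
  df
}

#' Compare enrichment profiles across entities
#'
#' Builds a long-format comparison of per-entity enrichment results:
#' per-(entity, pathway) gene ratios and per-(entity, class) counts of
#' significant pathways, suitable for bubble-plot export. Pathway classes
#' (orthology-style groupings) are an optional annotation input.
#'
#' @param rows_by_entity named list (>= 2 entries) of `enrichment_result`
#'   data frames.
#' @param class_map optional data frame (pathway_id, class_label).
#' @return List of class `profile_comparison` with `pathways` (long data
#'   frame: entity, pathway_id, class_label, overlap, gene_ratio,
#'   p_adjusted, significant) and `class_counts` (entity, class_label,
#'   n_significant; every entity retained even with zero counts).
#' @export
compare_profiles <- function(rows_by_entity, class_map = NULL) {
  stopifnot(is.list(rows_by_entity), length(rows_by_entity) >= 2,
            !is.null(names(rows_by_entity)))
  cls <- function(pid) {
    if (is.null(class_map)) return(rep(NA_character_, length(pid)))
    as.character(class_map[[2L]])[match(pid, as.character(class_map[[1L]]))]
  }
  long <- do.call(rbind, lapply(names(rows_by_entity), function(ent) {
    df <- rows_by_entity[[ent]]
    data.frame(entity = ent, pathway_id = df$pathway_id,
               class_label = cls(df$pathway_id), overlap = df$overlap,
               gene_ratio = df$gene_ratio, p_adjusted = df$p_adjusted,
               significant = df$significant, stringsAsFactors = FALSE)
  }))
  rownames(long) <- NULL
  sig <- long[long$significant, , drop = FALSE]
  counts <- do.call(rbind, lapply(names(rows_by_entity), function(ent) {
    s <- sig[sig$entity == ent, , drop = FALSE]
    if (nrow(s) == 0) {
      data.frame(entity = ent, class_label = NA_character_,
                 n_significant = 0L, stringsAsFactors = FALSE)
    } else {
      cl <- ifelse(is.na(s$class_label), "unclassified", s$class_label)
      agg <- stats::aggregate(list(n_significant = s$pathway_id),
                              by = list(class_label = cl),
                              FUN = length)
      data.frame(entity = ent, class_label = agg$class_label,
                 n_significant = agg$n_significant,
                 stringsAsFactors = FALSE)
    }
  }))
  rownames(counts) <- NULL
  structure(list(pathways = long, class_counts = counts),
            class = "profile_comparison")
}

#' @export
print.profile_comparison <- function(x, ...) {
  cat("Enrichment profile comparison: ",
      length(unique(x$pathways$entity)), " entities, ",
      length(unique(x$pathways$pathway_id)), " pathways\n", sep = "")
  print(x$class_counts)
  invisible(x)
}
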
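#' Assemble formula/herb/ingredient composition tables
#'
#' Bundles the three relations that connect a multi-herb formula to protein
#' targets (formula to herb, herb to ingredient, ingredient to target gene)
#' plus optional per-ingredient drug-likeness scores in \[0, 1\]. Herbs that
#' appear in a formula but have no ingredient rows are logged as
#' target-less rather than rejected.
#'
#' @param formula_herb data frame (formula_id, herb_id).
#' @param herb_ingredient data frame (herb_id, ingredient_id).
#' @param ingredient_target data frame (ingredient_id, gene).
#' @param druglikeness optional named numeric vector (names = ingredient
#'   ids) or two-column data frame (ingredient_id, score), scores in \[0, 1\].
#' @return An object of class `composition_tables`.
#' @export
composition_tables <- function(formula_herb, herb_ingredient,
                               ingredient_target, druglikeness = NULL) {
  fh <- as_pairs(formula_herb, c("formula_id", "herb_id"))
  hi <- as_pairs(herb_ingredient, c("herb_id", "ingredient_id"))
  it <- as_pairs(ingredient_target, c("ingredient_id", "gene"))
  if (!is.null(druglikeness)) {
    if (is.data.frame(druglikeness)) {
      druglikeness <- stats::setNames(as.numeric(druglikeness[[2L]]),
                                      as.character(druglikeness[[1L]]))
    }
    if (any(is.na(druglikeness)) ||
        any(druglikeness < 0) || any(druglikeness > 1)) {
      stop("drug-likeness scores must lie in [0, 1]")
    }
  }
  targetless <- setdiff(unique(fh$herb_id), unique(hi$herb_id))
  if (length(targetless)) {
    message("herb(s) without ingredient rows (target-less): ",
            paste(targetless, collapse = ", "))
  }
  structure(list(formula_herb = fh, herb_ingredient = hi,
                 ingredient_target = it, druglikeness = druglikeness),
            class = "composition_tables")
}

# normalize a two-column relation: character columns, unique rows
as_pairs <- function(df, nm) {
  stopifnot(is.data.frame(df) || is.matrix(df), ncol(df) >= 2)
  out <- data.frame(a = as.character(df[[1L]]), b = as.character(df[[2L]]),
                    stringsAsFactors = FALSE)
  out <- unique(out[!is.na(out$a) & !is.na(out$b) &
                      nzchar(out$a) & nzchar(out$b), , drop = FALSE])
  names(out) <- nm
  rownames(out) <- NULL
  out
}

#' @export
print.composition_tables <- function(x, ...) {
  cat("Composition tables:\n",
      "  formulae:    ", length(unique(x$formula_herb$formula_id)), "\n",
      "  herbs:       ", length(unique(x$formula_herb$herb_id)), "\n",
      "  ingredients: ", length(unique(x$herb_ingredient$ingredient_id)),
      "\n",
      "  target rows: ", nrow(x$ingredient_target), "\n", sep = "")
  cat("  drug-likeness scores: ",
      if (is.null(x$druglikeness)) "absent" else length(x$druglikeness),
      "\n", sep = "")
  invisible(x)
}

#' Read composition tables from TSV files
#'
#' @param formula_herb_path,herb_ingredient_path,ingredient_target_path
#'   paths to the three relation TSVs.
#' @param druglikeness_path optional path to a TSV (ingredient_id, score).
#' @param header logical; header rows in the TSVs (default `TRUE`).
#' @return A `composition_tables` object.
#' @export
read_composition <- function(formula_herb_path, herb_ingredient_path,
                             ingredient_target_path,
                             druglikeness_path = NULL, header = TRUE) {
  rd <- function(p) {
    if (!file.exists(p)) stop("composition file not found: ", p)
    utils::read.delim(p, header = header, sep = "\t",
                      colClasses = "character", quote = "",
                      stringsAsFactors = FALSE)
  }
  dl <- NULL
  if (!is.null(druglikeness_path)) {
    d <- rd(druglikeness_path)
    dl <- stats::setNames(as.numeric(d[[2L]]), as.character(d[[1L]]))
  }
  composition_tables(rd(formula_herb_path), rd(herb_ingredient_path),
                     rd(ingredient_target_path), dl)
}

#' Screen ingredients by drug-likeness score
#'
#' Removes ingredients whose drug-likeness score falls below `threshold`
#' from the herb-ingredient and ingredient-target relations. Ingredients
#' without a score are retained (they were never screened). With no scores
#' at all the operation is the identity, with a warning.
#'
#' @param tables a `composition_tables` object.
#' @param threshold score cut-off in \[0, 1\]; 0 disables screening.
#' @return Filtered `composition_tables` with attribute `n_removed`.
#' @export
filter_druglike <- function(tables, threshold) {
  stopifnot(inherits(tables, "composition_tables"))
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      is.na(threshold) || threshold < 0 || threshold > 1) {
    stop("drug-likeness threshold must be a single value in [0, 1]")
  }
  if (is.null(tables$druglikeness)) {
    warning("no drug-likeness scores present; screening skipped")
    attr(tables, "n_removed") <- 0L
    return(tables)
  }
  drop <- names(tables$druglikeness)[tables$druglikeness < threshold]
  out <- tables
  out$herb_ingredient <- tables$herb_ingredient[
    !(tables$herb_ingredient$ingredient_id %in% drop), , drop = FALSE]
  out$ingredient_target <- tables$ingredient_target[
    !(tables$ingredient_target$ingredient_id %in% drop), , drop = FALSE]
  out$druglikeness <- tables$druglikeness[
    !(names(tables$druglikeness) %in% drop)]
  message(length(drop), " ingredient(s) removed by drug-likeness screen at ",
          threshold)
  attr(out, "n_removed") <- length(drop)
  out
}

#' Assemble the target profile of one formula
#'
#' A formula's target set is the union over its herbs, their ingredients
#' and those ingredients' protein targets; an ingredient shared by several
#' herbs of the formula contributes its targets once (set semantics).
#' Provenance records every (herb, ingredient) pair contributing at least
#' one target. A formula left with zero targets is flagged unusable, not
#' rejected.
#'
#' @param tables a `composition_tables` object (post any drug-likeness
#'   screen).
#' @param formula_id identifier present in the formula-herb table.
#' @return An object of class `target_profile`: entity_id, entity_kind,
#'   targets (character vector), provenance (data frame herb_id,
#'   ingredient_id), usable flag.
#' @export
assemble_formula_targets <- function(tables, formula_id) {
  stopifnot(inherits(tables, "composition_tables"))
  fh <- tables$formula_herb
  if (!formula_id %in% fh$formula_id) {
    stop("unknown formula_id: ", formula_id)
  }
  herbs <- unique(fh$herb_id[fh$formula_id == formula_id])
  hi <- tables$herb_ingredient
  hi <- hi[hi$herb_id %in% herbs, , drop = FALSE]
  it <- tables$ingredient_target
  prov <- merge(hi, unique(it["ingredient_id"]), by = "ingredient_id")
  prov <- prov[order(prov$herb_id, prov$ingredient_id),
               c("herb_id", "ingredient_id")]
  rownames(prov) <- NULL
  targets <- sort(unique(
    it$gene[it$ingredient_id %in% hi$ingredient_id]))
  usable <- length(targets) > 0
  if (!usable) warning("formula ", formula_id, " has no targets; flagged unusable")
  structure(list(entity_id = formula_id, entity_kind = "formula",
                 targets = targets, provenance = prov, usable = usable),
            class = "target_profile")
}

#' @export
print.target_profile <- function(x, ...) {
  cat("Target profile '", x$entity_id, "' (", x$entity_kind, "): ",
      length(x$targets), " targets",
      if (!x$usable) " [UNUSABLE]" else "", "\n", sep = "")
  if (!is.null(x$provenance) && nrow(x$provenance)) {
    cat("  contributing (herb, ingredient) pairs: ", nrow(x$provenance),
        "\n", sep = "")
  }
  invisible(x)
}

#' Assemble target profiles for every formula in the tables
#'
#' @param tables a `composition_tables` object.
#' @return Named list of `target_profile` objects, in formula order of
#'   first appearance.
#' @export
assemble_all_formula_targets <- function(tables) {
  ids <- unique(tables$formula_herb$formula_id)
  stats::setNames(lapply(ids, function(f) {
    suppressWarnings(assemble_formula_targets(tables, f))
  }), ids)
}

#' Count distinct herbs across formulae
#'
#' @param tables a `composition_tables` object.
#' @param formula_ids non-empty character vector of formula identifiers.
#' @return Number of distinct herb identifiers used by the listed formulae.
#' @export
count_distinct_herbs <- function(tables, formula_ids) {
  stopifnot(inherits(tables, "composition_tables"), length(formula_ids) >= 1)
  fh <- tables$formula_herb
  unknown <- setdiff(formula_ids, fh$formula_id)
  if (length(unknown)) {
    stop("unknown formula_id(s): ", paste(unknown, collapse = ", "))
  }
  length(unique(fh$herb_id[fh$formula_id %in% formula_ids]))
}
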
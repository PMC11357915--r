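#' Read gene sets from a GMT or two-column TSV file
#'
#' GMT lines are `id<TAB>description<TAB>gene1<TAB>gene2...`. The TSV form
#' has columns `set_id`, `gene` and an optional third per-association
#' P-value column; when present, associations are screened at
#' `p_threshold` (mirroring databases that ship statistically verified
#' symptom-gene links).
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"gmt"` or `"tsv"`.
#' @param p_threshold P-value screen for the optional third TSV column
#'   (default 0.05).
#' @param header logical; TSV header row (default `FALSE`).
#' @return Named list of character vectors (one per set, duplicates
#'   collapsed), with set descriptions in the `"labels"` attribute. Sets
#'   that end up empty are dropped with a warning.
#' @export
read_gene_sets <- function(path, format = c("auto", "gmt", "tsv"),
                           p_threshold = 0.05, header = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("gene set file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.gmt$", path, ignore.case = TRUE)) "gmt" else "tsv"
  }
  if (format == "gmt") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    ids <- vapply(parts, `[`, "", 1L)
    labels <- vapply(parts, function(p) if (length(p) >= 2) p[2L] else "", "")
    sets <- lapply(parts, function(p) {
      unique(p[-(1:2)][nzchar(p[-(1:2)])])
    })
    names(sets) <- ids
  } else {
    df <- utils::read.delim(path, header = header, sep = "\t",
                            colClasses = "character", quote = "",
                            stringsAsFactors = FALSE)
    if (ncol(df) < 2) stop("gene set TSV needs at least two columns")
    if (ncol(df) >= 3) {
      p <- suppressWarnings(as.numeric(df[[3L]]))
      keep <- !is.na(p) & p < p_threshold
      df <- df[keep, , drop = FALSE]
    }
    sets <- lapply(split(df[[2L]], df[[1L]]), unique)
    labels <- stats::setNames(names(sets), names(sets))
  }
  empty <- lengths(sets) == 0
  if (any(empty)) {
    warning("dropping ", sum(empty), " empty gene set(s): ",
            paste(names(sets)[empty], collapse = ", "))
    sets <- sets[!empty]
    labels <- labels[!empty]
  }
  attr(sets, "labels") <- unname(labels)
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param labels optional descriptions (defaults to the set ids).
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(sets, path, labels = names(sets)) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], labels[i], sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
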
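# Plain-text interchange: GMT gene-set files, two-column ortholog maps,
# DEG lists, and JSON ground truth / reports.

#' Read and write GMT gene-set files
#'
#' One set per line: name, description, then member genes, tab
#' separated. The description field carries the injury class when one is
#' set (otherwise "na").
#'
#' @param path GMT file path.
#' @param collection A [module_collection()].
#' @return `read_gmt` returns a [module_collection()]; `write_gmt`
#'   invisibly returns `path`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  mods <- lapply(lines, function(ln) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3L)
      stop("malformed GMT line (need name, description, >= 1 gene): ",
           substr(ln, 1, 50), call. = FALSE)
    cls <- parts[2]
    list(name = parts[1],
         class = if (cls %in% INJURY_CLASSES) cls else NA_character_,
         genes = parts[-(1:2)])
  })
  module_collection(mods)
}

#' @rdname read_gmt
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "module_collection"))
  lines <- vapply(collection, function(m) {
    paste(c(m$name, if (is.na(m$class)) "na" else m$class, m$genes),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read and write two-column ortholog maps
#'
#' TSV with header `source_gene<TAB>target_gene`; many-to-many rows are
#' allowed and resolved at mapping time by [map_orthologs()].
#'
#' @param path TSV path.
#' @param map Data.frame with columns `source_gene`, `target_gene`.
#' @return `read_ortholog_map` returns the data.frame;
#'   `write_ortholog_map` invisibly returns `path`.
#' @export
read_ortholog_map <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  map <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("source_gene", "target_gene") %in% names(map)))
    stop("ortholog map needs columns 'source_gene' and 'target_gene'",
         call. = FALSE)
  map
}

#' @rdname read_ortholog_map
#' @export
write_ortholog_map <- function(map, path) {
  utils::write.table(map[, c("source_gene", "target_gene")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write one-ID-per-line gene lists
#'
#' @param genes Character vector of gene IDs.
#' @param path Text file path.
#' @return `read_gene_list` returns a character vector;
#'   `write_gene_list` invisibly returns `path`.
#' @export
write_gene_list <- function(genes, path) {
  writeLines(as.character(genes), path)
  invisible(path)
}

#' @rdname write_gene_list
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines[nzchar(lines)]
}

#' Write a module activation table
#'
#' TSV mirroring the published activation tables: module, injury class,
#' z-score, Fisher combined p, permutation p, coverage, and the
#' significance flag as a boolean column. Rows are grouped by injury
#' class (inflammation, proliferation, degeneration, then unclassed) and
#' ranked by z within class when `by_class = TRUE`, or globally ranked
#' by z otherwise.
#'
#' @param scores A `module_activation` table.
#' @param path TSV path.
#' @param by_class Group rows by injury class.
#' @return Invisibly, `path`.
#' @export
write_activation_table <- function(scores, path, by_class = TRUE) {
  stopifnot(inherits(scores, "module_activation"))
  out <- as.data.frame(scores)
  if (by_class) {
    cls <- factor(out$class, levels = INJURY_CLASSES)
    out <- out[order(cls, -out$z, na.last = TRUE), ]
  }
  cols <- c("module", "class", "aafc", "z", "fisher_p", "p_perm",
            "n_measured", "coverage", "low_coverage", "significant")
  utils::write.table(out[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
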
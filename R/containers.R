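#' Construct an expression experiment
#'
#' Container for one system-condition: a genes x samples matrix of
#' log-transformed expression values plus per-sample cohort labels
#' (treatment / control) and free-form metadata (system, dose, time).
#'
#' @param values Numeric matrix, genes in rows, samples in columns.
#'   Row names are gene identifiers, column names sample identifiers.
#' @param cohort Character/factor vector, one of `"treatment"` or
#'   `"control"` per sample (named or in column order).
#' @param meta Named list of condition metadata (system, dose, time...).
#' @return An object of class `expression_experiment` with elements
#'   `values`, `gene_ids`, `sample_ids`, `cohort`, `meta`.
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("G", 1:3), paste0("S", 1:4)))
#' expression_experiment(m, c("treatment", "treatment", "control", "control"))
#' @export
expression_experiment <- function(values, cohort, meta = list()) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix (genes x samples)", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must carry gene row names and sample column names",
         call. = FALSE)
  gene_ids <- rownames(values)
  sample_ids <- colnames(values)
  if (anyDuplicated(gene_ids))
    stop("duplicate gene IDs: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "),
         call. = FALSE)
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite expression value at gene '%s', sample '%s'",
                 gene_ids[bad[1]], sample_ids[bad[2]]), call. = FALSE)
  }
  cohort_names <- names(cohort)
  cohort <- as.character(cohort)
  names(cohort) <- cohort_names
  if (!is.null(names(cohort))) {
    missing <- setdiff(sample_ids, names(cohort))
    if (length(missing))
      stop("sample(s) without cohort label: ",
           paste(missing, collapse = ", "), call. = FALSE)
    cohort <- cohort[sample_ids]
  }
  if (length(cohort) != length(sample_ids))
    stop("`cohort` must label every sample", call. = FALSE)
  if (!all(cohort %in% c("treatment", "control")))
    stop("cohort labels must be 'treatment' or 'control'; got: ",
         paste(setdiff(unique(cohort), c("treatment", "control")),
               collapse = ", "), call. = FALSE)
  counts <- table(factor(cohort, levels = c("treatment", "control")))
  if (any(counts < 2L))
    stop("each cohort needs at least 2 samples (treatment: ",
         counts[["treatment"]], ", control: ", counts[["control"]], ")",
         call. = FALSE)
  structure(
    list(values = values, gene_ids = gene_ids, sample_ids = sample_ids,
         cohort = unname(cohort), meta = meta),
    class = "expression_experiment"
  )
}

#' @export
print.expression_experiment <- function(x, ...) {
  counts <- table(x$cohort)
  cat(sprintf(
    "<expression_experiment> %d genes x %d samples (%s treatment, %s control)\n",
    length(x$gene_ids), length(x$sample_ids),
    counts[["treatment"]], counts[["control"]]))
  if (length(x$meta))
    cat("  meta:", paste(names(x$meta), unlist(x$meta), sep = "=",
                         collapse = ", "), "\n")
  invisible(x)
}

#' Construct a module collection
#'
#' A named list of gene sets, each tagged with an injury class
#' (inflammation / proliferation / degeneration, or NA for generic sets).
#'
#' @param modules List of lists with elements `name`, `genes` (character,
#'   non-empty) and optional `class`.
#' @return An object of class `module_collection` (a named list).
#' @examples
#' module_collection(list(
#'   list(name = "Fibrogenesis", class = "inflammation",
#'        genes = c("G1", "G2", "G3"))))
#' @export
module_collection <- function(modules) {
  if (!length(modules)) stop("empty module collection", call. = FALSE)
  modules <- lapply(modules, function(m) {
    if (is.null(m$name) || !nzchar(m$name))
      stop("every module needs a non-empty name", call. = FALSE)
    genes <- unique(as.character(m$genes))
    if (!length(genes))
      stop(sprintf("module '%s' has an empty gene set", m$name),
           call. = FALSE)
    cls <- if (is.null(m$class)) NA_character_ else as.character(m$class)
    if (!is.na(cls) && !cls %in% INJURY_CLASSES)
      stop(sprintf("module '%s': unknown injury class '%s'", m$name, cls),
           call. = FALSE)
    list(name = m$name, class = cls, genes = genes)
  })
  nms <- vapply(modules, `[[`, character(1), "name")
  if (anyDuplicated(nms))
    stop("duplicate module names: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "), call. = FALSE)
  names(modules) <- nms
  structure(modules, class = "module_collection")
}

#' @export
print.module_collection <- function(x, ...) {
  sizes <- vapply(x, function(m) length(m$genes), integer(1))
  cat(sprintf("<module_collection> %d modules, sizes %d-%d\n",
              length(x), min(sizes), max(sizes)))
  invisible(x)
}

#' Assemble a fold-change table
#'
#' Per-gene results for one condition: log fold change (treatment mean
#' minus control mean, natural-log scale), two-sided t-test p-value and
#' BH-adjusted q-value. Normally produced by [compute_fc()]; this
#' constructor also lets externally computed effect estimates (for
#' example bootstrap-based beta values) be injected in place of the
#' mean-log-difference fold change.
#'
#' @param gene_id Character vector of unique gene identifiers.
#' @param fc Numeric log fold changes.
#' @param t_p Two-sided t-test p-values (NA allowed, e.g. zero-variance
#'   genes).
#' @param q BH-adjusted p-values; recomputed from `t_p` when omitted.
#' @param zero_var Logical flag per gene: within-cohort variance was zero
#'   so no t-test was possible.
#' @return A data.frame of class `fc_table`.
#' @export
fc_table <- function(gene_id, fc, t_p = NA_real_, q = NULL,
                     zero_var = FALSE) {
  gene_id <- as.character(gene_id)
  if (anyDuplicated(gene_id))
    stop("duplicate gene IDs in fold-change table", call. = FALSE)
  n <- length(gene_id)
  fc <- as.numeric(fc)
  if (length(fc) != n || any(!is.finite(fc)))
    stop("`fc` must be finite and match `gene_id` in length", call. = FALSE)
  t_p <- rep_len(as.numeric(t_p), n)
  if (any(t_p < 0 | t_p > 1, na.rm = TRUE))
    stop("t-test p-values must lie in [0, 1]", call. = FALSE)
  if (is.null(q)) q <- adjust_fdr(t_p)
  zero_var <- rep_len(as.logical(zero_var), n)
  structure(
    data.frame(gene_id = gene_id, fc = fc, t_p = t_p, q = q,
               zero_var = zero_var, stringsAsFactors = FALSE),
    class = c("fc_table", "data.frame")
  )
}
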
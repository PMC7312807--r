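# Per-gene statistics: fold changes as differences of mean log
# expression, two-sample t-tests, BH adjustment, and DEG calling with
# the q <= 0.05 / |log FC| >= 0.41 (fold change 1.5) convention.

#' Load an expression experiment from TSV files
#'
#' @param matrix_path TSV, first column gene IDs, remaining columns one
#'   sample each (header row = sample IDs), log-expression values.
#' @param cohort_path TSV with columns `sample_id` and `cohort`
#'   (`treatment` / `control`).
#' @param meta Named list of condition metadata.
#' @return An [expression_experiment()].
#' @export
load_experiment <- function(matrix_path, cohort_path, meta = list()) {
  for (p in c(matrix_path, cohort_path))
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  tab <- utils::read.delim(matrix_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2L)
    stop("expression matrix needs a gene column plus >= 1 sample",
         call. = FALSE)
  gene_ids <- as.character(tab[[1]])
  if (anyDuplicated(gene_ids))
    stop("duplicated gene row(s): ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "),
         call. = FALSE)
  values <- tab[, -1, drop = FALSE]
  for (j in seq_along(values)) {
    col <- values[[j]]
    if (!is.numeric(col)) {
      suppressWarnings(num <- as.numeric(col))
      if (anyNA(num)) {
        bad <- which(is.na(num))[1]
        stop(sprintf(
          "non-numeric expression value '%s' at gene '%s', sample '%s'",
          col[bad], gene_ids[bad], colnames(values)[j]), call. = FALSE)
      }
      values[[j]] <- num
    }
  }
  values <- as.matrix(values)
  rownames(values) <- gene_ids
  cohorts <- utils::read.delim(cohort_path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "cohort") %in% names(cohorts)))
    stop("cohort file needs columns 'sample_id' and 'cohort'",
         call. = FALSE)
  cohort <- stats::setNames(cohorts$cohort, cohorts$sample_id)
  expression_experiment(values, cohort, meta = meta)
}

#' Write an expression experiment to TSV files
#'
#' @param exp An [expression_experiment()].
#' @param matrix_path,cohort_path Output paths (see [load_experiment()]
#'   for the format).
#' @return Invisibly, the two paths.
#' @export
write_experiment <- function(exp, matrix_path, cohort_path) {
  stopifnot(inherits(exp, "expression_experiment"))
  tab <- data.frame(gene_id = exp$gene_ids, exp$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(
    data.frame(sample_id = exp$sample_ids, cohort = exp$cohort),
    cohort_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(matrix_path, cohort_path))
}

#' Per-gene fold changes and t-tests
#'
#' The fold change of a gene is the difference between the mean
#' log-transformed expression of the treatment and control cohorts
#' (natural-log scale, so 0.41 corresponds to a 1.5-fold change).
#' Significance comes from a two-sided two-sample t-test — pooled
#' variance (Student) by default, Welch by flag — and q-values from
#' Benjamini-Hochberg adjustment across all genes. Genes whose pooled
#' within-cohort variance is zero keep their fold change but get a
#' missing p-value and a `zero_var` flag.
#'
#' @param exp An [expression_experiment()].
#' @param var_equal Pooled-variance Student's t (default) or Welch.
#' @return An `fc_table` data.frame: gene_id, fc, t_p, q, zero_var.
#' @examples
#' sim <- generate_experiment(simulation_config(100, seed = 1))
#' head(compute_fc(sim$experiment))
#' @export
compute_fc <- function(exp, var_equal = TRUE) {
  stopifnot(inherits(exp, "expression_experiment"))
  trt <- exp$values[, exp$cohort == "treatment", drop = FALSE]
  ctl <- exp$values[, exp$cohort == "control", drop = FALSE]
  n1 <- ncol(trt); n2 <- ncol(ctl)
  m1 <- rowMeans(trt); m2 <- rowMeans(ctl)
  v1 <- rowSums((trt - m1)^2) / (n1 - 1)
  v2 <- rowSums((ctl - m2)^2) / (n2 - 1)
  fc <- m1 - m2
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep.int(n1 + n2 - 2, length(fc))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  zero_var <- se == 0
  t_stat <- ifelse(zero_var, NA_real_, fc / se)
  t_p <- ifelse(zero_var, NA_real_, 2 * stats::pt(-abs(t_stat), df))
  fc_table(exp$gene_ids, fc, t_p, zero_var = zero_var)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted p-values (q-values); missing p-values stay missing
#' and do not enter the adjustment.
#'
#' @param p_values Numeric vector in `[0, 1]`, NA allowed.
#' @return q-values in the input order.
#' @examples
#' adjust_fdr(c(0.01, 0.02, 0.03, 0.04))
#' @export
adjust_fdr <- function(p_values) {
  p <- as.numeric(p_values)
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' DEG calling criteria
#'
#' Defaults are q <= 0.05 with a minimum absolute log effect of 0.41
#' natural-log units, i.e. a 1.5-fold change. `log_base` converts
#' `effect_min` when fold changes were computed in another base.
#'
#' @param q_max FDR threshold in (0, 1).
#' @param effect_min Minimum `|log fold change|`, natural-log scale.
#' @param log_base Base of the fold-change column the criteria will be
#'   applied to; `effect_min` is rescaled accordingly.
#' @return An object of class `deg_criteria`.
#' @export
deg_criteria <- function(q_max = 0.05, effect_min = 0.41,
                         log_base = exp(1)) {
  if (q_max <= 0 || q_max >= 1) stop("q_max must be in (0, 1)",
                                     call. = FALSE)
  if (effect_min < 0) stop("effect_min must be >= 0", call. = FALSE)
  structure(list(q_max = q_max,
                 effect_min = effect_min / log(log_base),
                 log_base = log_base),
            class = "deg_criteria")
}

#' Call differentially expressed genes
#'
#' A gene is a DEG when `q <= q_max` and `|fc| >= effect_min`.
#'
#' @param fc_tab An `fc_table` from [compute_fc()].
#' @param criteria A [deg_criteria()].
#' @return Data.frame of DEGs with columns gene_id, fc, q and
#'   `direction` (`"up"` / `"down"`); zero rows when nothing passes.
#' @export
call_degs <- function(fc_tab, criteria = deg_criteria()) {
  stopifnot(inherits(fc_tab, "fc_table"), inherits(criteria, "deg_criteria"))
  keep <- !is.na(fc_tab$q) & fc_tab$q <= criteria$q_max &
    abs(fc_tab$fc) >= criteria$effect_min
  out <- fc_tab[keep, c("gene_id", "fc", "q")]
  out$direction <- ifelse(out$fc >= 0, "up", "down")
  rownames(out) <- NULL
  out
}

#' Read/write fold-change tables
#'
#' @param fc_tab An `fc_table`.
#' @param path TSV path.
#' @return `write_fc_table` invisibly returns `path`; `read_fc_table`
#'   returns an `fc_table`.
#' @export
write_fc_table <- function(fc_tab, path) {
  utils::write.table(fc_tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_fc_table
#' @export
read_fc_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  fc_table(tab$gene_id, tab$fc, tab$t_p, q = tab$q,
           zero_var = tab$zero_var %||% FALSE)
}
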
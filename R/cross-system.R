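# Cross-species / cross-system comparison layer: ortholog mapping, DEG
# overlap against chance expectation, Pearson correlation of module
# activation vectors, condition-level PCA, and hypergeometric gene-set
# enrichment.

#' Map a gene set through an ortholog table
#'
#' @param genes Character vector of source-namespace gene IDs.
#' @param map Data.frame with columns `source_gene` and `target_gene`
#'   (many-to-many allowed).
#' @param policy `"one_to_one"` (default): each source contributes at
#'   most one target and each target appears at most once, ties broken
#'   lexicographically; `"any"`: every reachable target is kept.
#' @return List with `mapped` (target IDs), `n_unmapped` (sources with
#'   no ortholog) and `n_collapsed` (mappings dropped by the one-to-one
#'   policy).
#' @examples
#' map <- data.frame(source_gene = c("a", "b"), target_gene = c("x", "x"))
#' map_orthologs(c("a", "b"), map)  # one target, one collapse
#' @export
map_orthologs <- function(genes, map, policy = c("one_to_one", "any")) {
  policy <- match.arg(policy)
  if (!all(c("source_gene", "target_gene") %in% names(map)))
    stop("ortholog map needs columns 'source_gene' and 'target_gene'",
         call. = FALSE)
  if (!nrow(map)) stop("ortholog map is empty", call. = FALSE)
  if (any(!nzchar(map$source_gene)) || any(!nzchar(map$target_gene)) ||
      anyNA(map$source_gene) || anyNA(map$target_gene))
    stop("ortholog map contains null IDs", call. = FALSE)
  genes <- unique(as.character(genes))
  hits <- map[map$source_gene %in% genes, c("source_gene", "target_gene")]
  n_unmapped <- length(setdiff(genes, hits$source_gene))
  if (policy == "any") {
    mapped <- sort(unique(hits$target_gene))
    return(list(mapped = mapped, n_unmapped = n_unmapped,
                n_collapsed = 0L))
  }
  hits <- hits[order(hits$source_gene, hits$target_gene), ]
  hits <- hits[!duplicated(hits$source_gene), ]   # one target per source
  dup_target <- duplicated(hits$target_gene)      # one source per target
  list(mapped = sort(unique(hits$target_gene)),
       n_unmapped = n_unmapped,
       n_collapsed = sum(dup_target))
}

#' DEG-set overlap with the counts expected by chance
#'
#' Exact Venn region counts for 2 or 3 gene sets, together with the
#' overlap expected under independent uniform sampling from a universe
#' of `universe_size` genes: `|A||B|/N` pairwise (the hypergeometric
#' mean) and `|A||B||C|/N^2` for the triple.
#'
#' @param sets Named list of 2 or 3 character vectors.
#' @param universe_size Number of genes in the shared universe; must be
#'   at least the size of the union.
#' @return Object of class `overlap_report`: `regions` (exclusive Venn
#'   region counts, names like `"A&B"`), `observed` and `expected`
#'   (pairwise and highest-order intersection counts), `set_sizes`,
#'   `universe_size`.
#' @examples
#' overlap_with_expectation(
#'   list(A = letters[1:20], B = letters[6:20]), universe_size = 26)
#' @export
overlap_with_expectation <- function(sets, universe_size) {
  if (!is.list(sets) || length(sets) < 2L || length(sets) > 3L)
    stop("`sets` must be a list of 2 or 3 gene sets", call. = FALSE)
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    names(sets) <- LETTERS[seq_along(sets)]
  sets <- lapply(sets, function(s) unique(as.character(s)))
  union_all <- unique(unlist(sets))
  if (universe_size < length(union_all))
    stop("universe_size is smaller than the union of the sets",
         call. = FALSE)
  member <- vapply(sets, function(s) union_all %in% s,
                   logical(length(union_all)))
  member <- matrix(member, ncol = length(sets),
                   dimnames = list(NULL, names(sets)))
  pattern <- apply(member, 1, function(row)
    paste(names(sets)[row], collapse = "&"))
  regions <- table(pattern)
  regions <- stats::setNames(as.integer(regions), names(regions))

  sizes <- vapply(sets, length, integer(1))
  nm <- names(sets)
  pairs <- utils::combn(seq_along(sets), 2L, simplify = FALSE)
  observed <- expected <- numeric(0)
  for (p in pairs) {
    key <- paste(nm[p], collapse = "&")
    observed[key] <- length(intersect(sets[[p[1]]], sets[[p[2]]]))
    expected[key] <- sizes[p[1]] * sizes[p[2]] / universe_size
  }
  if (length(sets) == 3L) {
    key <- paste(nm, collapse = "&")
    observed[key] <- length(Reduce(intersect, sets))
    expected[key] <- prod(sizes) / universe_size^2
  }
  structure(
    list(regions = regions, observed = observed, expected = expected,
         set_sizes = sizes, universe_size = universe_size),
    class = "overlap_report"
  )
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("<overlap_report> universe %d, sets: %s\n", x$universe_size,
              paste(names(x$set_sizes), x$set_sizes, sep = "=",
                    collapse = ", ")))
  for (k in names(x$observed))
    cat(sprintf("  %s: observed %d, expected by chance %.1f\n", k,
                x$observed[[k]], x$expected[[k]]))
  invisible(x)
}

#' Bundle a module activation vector for comparison
#'
#' @param system System label (e.g. "human_ivt").
#' @param condition Condition label (dose, time).
#' @param modules Ordered module names.
#' @param z Module activation z-scores, same order.
#' @return Object of class `activation_vector`.
#' @export
activation_vector <- function(system, condition, modules, z) {
  modules <- as.character(modules)
  z <- as.numeric(z)
  if (length(modules) != length(z))
    stop("modules and z must have equal length", call. = FALSE)
  if (anyDuplicated(modules))
    stop("duplicate module names in activation vector", call. = FALSE)
  structure(list(system = system, condition = condition,
                 modules = modules, z = z),
            class = "activation_vector")
}

#' @rdname activation_vector
#' @param scores A `module_activation` table from [score_all_modules()].
#' @export
as_activation_vector <- function(scores, system = "system",
                                 condition = "condition") {
  stopifnot(inherits(scores, "module_activation"))
  ord <- order(scores$module)
  activation_vector(system, condition, scores$module[ord],
                    scores$z[ord])
}

#' Pearson correlation between two module activation vectors
#'
#' Requires identical module ordering and at least 3 modules. The
#' p-value comes from the t-transform with n - 2 degrees of freedom,
#' one-sided for positive correlation (concordant activation).
#'
#' @param a,b [activation_vector()] objects over the same modules.
#' @return List with `r`, `p`, `n`.
#' @export
correlate_activation <- function(a, b) {
  stopifnot(inherits(a, "activation_vector"),
            inherits(b, "activation_vector"))
  if (!identical(a$modules, b$modules))
    stop("activation vectors must share the same module ordering",
         call. = FALSE)
  n <- length(a$modules)
  if (n < 3L)
    stop("at least 3 modules are needed for a correlation", call. = FALSE)
  for (v in list(a, b))
    if (anyNA(v$z) || stats::var(v$z) == 0)
      stop(sprintf(
        "activation vector of system '%s' has missing z-scores or zero variance",
        v$system), call. = FALSE)
  ct <- stats::cor.test(a$z, b$z, method = "pearson",
                        alternative = "greater")
  list(r = unname(ct$estimate), p = ct$p.value, n = n)
}

#' Principal component analysis of condition profiles
#'
#' Rows are conditions (system x dose x time), columns are features:
#' per-gene fold changes, pathway activation, or module activation
#' z-scores depending on `mode`. Features are centred; unit-variance
#' scaling is off by default (module z-scores are already on a common
#' scale) and available by flag. Rank-deficient input simply yields
#' trailing zero-variance components.
#'
#' @param features Numeric matrix, conditions x features, with row
#'   names identifying conditions.
#' @param mode Label recorded in the result: `"module"`, `"gene-FC"` or
#'   `"pathway"`.
#' @param standardize Scale features to unit variance (constant features
#'   are left unscaled).
#' @return Object of class `pca_result`: `coordinates` (conditions x
#'   components), `explained` (fraction of variance per component,
#'   summing to 1 for non-degenerate input), `sdev`, `mode`.
#' @export
pca_conditions <- function(features, mode = c("module", "gene-FC",
                                              "pathway"),
                           standardize = FALSE) {
  mode <- match.arg(mode)
  features <- as.matrix(features)
  if (nrow(features) < 2L || ncol(features) < 2L)
    stop("need at least 2 conditions and 2 features", call. = FALSE)
  if (any(!is.finite(features)))
    stop("features must be finite", call. = FALSE)
  if (standardize) {
    sds <- apply(features, 2, stats::sd)
    sds[sds == 0] <- 1
    features <- sweep(features, 2, sds, "/")
  }
  pc <- stats::prcomp(features, center = TRUE, scale. = FALSE)
  total <- sum(pc$sdev^2)
  explained <- if (total > 0) pc$sdev^2 / total else
    rep(0, length(pc$sdev))
  structure(
    list(coordinates = pc$x, explained = explained, sdev = pc$sdev,
         mode = mode),
    class = "pca_result"
  )
}

#' Hypergeometric gene-set enrichment
#'
#' Upper-tail hypergeometric test of each collection set's overlap with
#' a DEG list against a gene universe, with BH adjustment across sets.
#' Generic plumbing for user-supplied collections (e.g. pathway GMTs);
#' set genes outside the universe are ignored.
#'
#' @param deg_set Character vector of DEG IDs, a subset of `universe`.
#' @param universe Character vector of all measured gene IDs.
#' @param collection A [module_collection()].
#' @return Data.frame: set, class, set_size (in-universe), overlap,
#'   fold_enrichment, p, q — ordered by p.
#' @export
enrich_genesets <- function(deg_set, universe, collection) {
  stopifnot(inherits(collection, "module_collection"))
  universe <- unique(as.character(universe))
  if (!length(universe)) stop("empty gene universe", call. = FALSE)
  deg_set <- unique(as.character(deg_set))
  if (length(setdiff(deg_set, universe)))
    stop("deg_set contains genes outside the universe", call. = FALSE)
  n_univ <- length(universe)
  n_deg <- length(deg_set)
  rows <- lapply(collection, function(mod) {
    set_in <- intersect(mod$genes, universe)
    k <- length(intersect(set_in, deg_set))
    m <- length(set_in)
    p <- if (m == 0L) 1 else
      stats::phyper(k - 1, m, n_univ - m, n_deg, lower.tail = FALSE)
    fold <- if (m == 0L || n_deg == 0L) NA_real_ else
      (k / n_deg) / (m / n_univ)
    data.frame(set = mod$name, class = mod$class, set_size = m,
               overlap = k, fold_enrichment = fold, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- adjust_fdr(out$p)
  out <- out[order(out$p, out$set), ]
  rownames(out) <- NULL
  out
}
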
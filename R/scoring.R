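# The AAFC module activation score and its inference machinery.
#
# Observed score: sum over a module's measured genes of |log fold
# change|. Null: scores of equally sized gene sets drawn uniformly
# without replacement from the measured universe (default 10,000 draws,
# or exhaustive enumeration on small universes). The z-score standardises
# the observed score against that null and ranks modules; the empirical
# p-value is the add-one-smoothed upper tail. Fisher's method combines
# the member genes' t-test p-values as a reliability indicator, and a
# module is called significantly activated when the permutation p-value
# is below `alpha` (0.05) and the Fisher combined value below
# `fisher_max` (0.01).

#' Aggregate absolute fold-change score of a gene set
#'
#' Sum (or mean, by flag) of absolute log fold changes over the set's
#' genes that are present in the fold-change table. Duplicated IDs in
#' the set count once; the score is invariant to the sign of every fold
#' change and to gene order.
#'
#' @param fc_tab An `fc_table`.
#' @param genes Character vector of member gene IDs.
#' @param summarise `"sum"` (default) or `"mean"`. The z-score downstream
#'   is identical under either choice at fixed set size.
#' @param set_name Name used in error messages.
#' @return The score (single number).
#' @examples
#' tab <- fc_table(c("a", "b", "c"), c(1, -0.5, 0.25), t_p = 0.5)
#' aafc_score(tab, c("a", "b", "c"))  # 1.75
#' @export
aafc_score <- function(fc_tab, genes, summarise = c("sum", "mean"),
                       set_name = "gene set") {
  summarise <- match.arg(summarise)
  stopifnot(inherits(fc_tab, "fc_table"))
  genes <- unique(as.character(genes))
  hit <- fc_tab$fc[match(genes, fc_tab$gene_id)]
  hit <- hit[!is.na(hit)]
  if (!length(hit))
    stop(sprintf("no gene of '%s' is measured in the fold-change table",
                 set_name), call. = FALSE)
  if (summarise == "sum") sum(abs(hit)) else mean(abs(hit))
}

#' Permutation null distribution of AAFC scores
#'
#' Draws `B` gene sets of `set_size` genes uniformly without replacement
#' from the measured universe and scores each. On small problems
#' (`exhaustive = TRUE`) every subset is enumerated instead, giving the
#' exact null. The stored `sd` is the population standard deviation of
#' the draws, matching the exhaustive definition.
#'
#' @param fc_tab An `fc_table`.
#' @param set_size Genes per draw; must not exceed the universe.
#' @param B Number of draws (default 10,000).
#' @param seed Integer seed for reproducible draws.
#' @param exhaustive Enumerate all `choose(n, set_size)` subsets.
#' @param summarise Passed to the score, `"sum"` or `"mean"`.
#' @return Object of class `null_distribution`: list with `draws`,
#'   `mean`, `sd`, `B`, `set_size`, `exhaustive`.
#' @examples
#' tab <- fc_table(letters[1:4], 1:4, t_p = 0.5)
#' permutation_null(tab, 2, exhaustive = TRUE)$mean  # 5
#' @export
permutation_null <- function(fc_tab, set_size, B = 10000L, seed = NULL,
                             exhaustive = FALSE,
                             summarise = c("sum", "mean")) {
  summarise <- match.arg(summarise)
  stopifnot(inherits(fc_tab, "fc_table"))
  afc <- abs(fc_tab$fc)
  n <- length(afc)
  set_size <- as.integer(set_size)
  if (set_size < 1L) stop("set_size must be positive", call. = FALSE)
  if (set_size > n)
    stop(sprintf("set_size (%d) exceeds the measured universe (%d)",
                 set_size, n), call. = FALSE)
  agg <- if (summarise == "sum") sum else mean
  if (exhaustive) {
    draws <- as.vector(utils::combn(afc, set_size, agg))
  } else {
    if (B < 1L) stop("B must be >= 1", call. = FALSE)
    draws <- with_seed(seed, vapply(
      seq_len(B), function(i) agg(afc[sample.int(n, set_size)]),
      numeric(1)))
  }
  mu <- mean(draws)
  sdev <- sqrt(mean((draws - mu)^2))
  structure(
    list(draws = draws, mean = mu, sd = sdev, B = length(draws),
         set_size = set_size, exhaustive = exhaustive, seed = seed),
    class = "null_distribution"
  )
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("<null_distribution> %s%d draws, set size %d, mean %.4g, sd %.4g\n",
              if (x$exhaustive) "exhaustive " else "", x$B, x$set_size,
              x$mean, x$sd))
  invisible(x)
}

#' Standardise an observed module score against its permutation null
#'
#' `z = (observed - mean) / sd` of the null, and the empirical upper-tail
#' p-value with add-one smoothing: `(#\{draws > observed\} + 1) / (B + 1)`,
#' so it is never exactly zero. A degenerate null (sd 0) leaves z missing
#' but still yields the p-value.
#'
#' @param observed Observed AAFC score.
#' @param null A `null_distribution`.
#' @return List with `z` and `p_perm`.
#' @export
module_z_and_p <- function(observed, null) {
  stopifnot(inherits(null, "null_distribution"), is.numeric(observed))
  z <- if (null$sd > 0) (observed - null$mean) / null$sd else NA_real_
  p_perm <- (sum(null$draws > observed) + 1) / (null$B + 1)
  list(z = z, p_perm = p_perm)
}

#' Fisher's combined probability
#'
#' Combines k independent p-values through `X = -2 * sum(log(p))`, which
#' is chi-square with 2k degrees of freedom under the joint null; the
#' combined p-value is the upper tail of that distribution. Missing
#' values are dropped (their count is attached as attribute
#' `n_dropped`); a zero p-value is clamped to the smallest positive
#' double with a warning.
#'
#' @param p_values Numeric p-values in `[0, 1]`, NA allowed.
#' @return Combined p-value, with attributes `statistic` (X), `df` and
#'   `n_dropped`.
#' @examples
#' fisher_combined(c(0.05, 0.05))  # ~0.0175
#' @export
fisher_combined <- function(p_values) {
  p <- as.numeric(p_values)
  n_dropped <- sum(is.na(p))
  p <- p[!is.na(p)]
  if (!length(p))
    stop("no usable p-values to combine", call. = FALSE)
  if (any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  if (any(p == 0)) {
    warning("zero p-value(s) clamped to the smallest positive double")
    p[p == 0] <- .Machine$double.xmin
  }
  x <- -2 * sum(log(p))
  df <- 2L * length(p)
  structure(stats::pchisq(x, df = df, lower.tail = FALSE),
            statistic = x, df = df, n_dropped = n_dropped)
}

#' Joint significance call for a module
#'
#' A module is significantly activated when its activation p-value is
#' below `alpha` and its Fisher combined value below `fisher_max`.
#' Activation is one-sided: only scores above the null mean can be
#' significant, so a negative z never passes. When the permutation
#' p-value is not supplied, the normal upper tail of the z-score is used
#' (z > 1.645 at the default alpha).
#'
#' @param z Module z-score.
#' @param fisher_p Fisher combined p-value.
#' @param p_perm Empirical permutation p-value, if available.
#' @param alpha Activation p-value threshold (default 0.05).
#' @param fisher_max Fisher threshold (default 0.01).
#' @return Logical flag.
#' @examples
#' classify_module(2.1, 2.3e-20)  # TRUE
#' classify_module(2.8, 0.74)     # FALSE: unreliable member fold changes
#' classify_module(1.6, 6.6e-29)  # FALSE: activation not significant
#' @export
classify_module <- function(z, fisher_p, p_perm = NULL, alpha = 0.05,
                            fisher_max = 0.01) {
  p_act <- if (is.null(p_perm) || is.na(p_perm)) {
    if (is.na(z)) return(NA)
    stats::pnorm(z, lower.tail = FALSE)
  } else p_perm
  act <- p_act < alpha && (is.na(z) || z > 0)
  isTRUE(act && fisher_p < fisher_max)
}

#' Score every module of a collection
#'
#' Runs the full activation analysis per module: AAFC score, permutation
#' null of matched size (a deterministic substream seeded from the root
#' seed and the module name, so results do not depend on collection
#' order), z-score, empirical p-value, Fisher combined p-value over the
#' member genes' t-test p-values (zero-variance genes excluded), and the
#' joint significance flag. Modules covering less than `min_coverage` of
#' their genes are scored but flagged low-coverage. A module with no
#' measured gene yields an NA row and a warning; the others are still
#' scored.
#'
#' @param fc_tab An `fc_table`.
#' @param collection A [module_collection()].
#' @param B Permutation draws per module (default 10,000).
#' @param seed Root seed.
#' @param alpha,fisher_max Significance thresholds (0.05 / 0.01).
#' @param min_coverage Low-coverage flag threshold (fraction measured,
#'   default 0.3).
#' @param summarise `"sum"` or `"mean"` AAFC variant.
#' @return A `module_activation` data.frame, ranked by decreasing z:
#'   module, class, n_genes, n_measured, coverage, low_coverage, aafc,
#'   z, p_perm, fisher_p, significant.
#' @examples
#' sim <- generate_experiment(simulation_config(300, modules = list(
#'   module_spec("Fibrogenesis", 30, effect = 1, class = "inflammation"),
#'   module_spec("Dilatation", 30, effect = 0, class = "degeneration")),
#'   seed = 2))
#' tab <- compute_fc(sim$experiment)
#' coll <- module_collection(lapply(names(sim$truth$members), function(nm)
#'   list(name = nm, genes = sim$truth$members[[nm]])))
#' score_all_modules(tab, coll, B = 500, seed = 1)
#' @export
score_all_modules <- function(fc_tab, collection, B = 10000L, seed = 1L,
                              alpha = 0.05, fisher_max = 0.01,
                              min_coverage = 0.3,
                              summarise = c("sum", "mean")) {
  summarise <- match.arg(summarise)
  stopifnot(inherits(fc_tab, "fc_table"),
            inherits(collection, "module_collection"))
  rows <- lapply(collection, function(mod) {
    genes <- unique(mod$genes)
    idx <- match(genes, fc_tab$gene_id)
    measured <- idx[!is.na(idx)]
    n_meas <- length(measured)
    base <- data.frame(
      module = mod$name, class = mod$class, n_genes = length(genes),
      n_measured = n_meas, coverage = n_meas / length(genes),
      low_coverage = n_meas / length(genes) < min_coverage,
      aafc = NA_real_, z = NA_real_, p_perm = NA_real_,
      fisher_p = NA_real_, significant = NA,
      stringsAsFactors = FALSE)
    if (n_meas == 0L) {
      warning(sprintf("module '%s': no measured genes; skipped", mod$name))
      return(base)
    }
    obs <- aafc_score(fc_tab, genes, summarise = summarise,
                      set_name = mod$name)
    null <- permutation_null(fc_tab, n_meas, B = B,
                             seed = string_seed(seed, mod$name),
                             summarise = summarise)
    zp <- module_z_and_p(obs, null)
    pv <- fc_tab$t_p[measured]
    pv <- pv[!is.na(pv) & !fc_tab$zero_var[measured]]
    fish <- if (length(pv)) as.numeric(fisher_combined(pv)) else NA_real_
    base$aafc <- obs
    base$z <- zp$z
    base$p_perm <- zp$p_perm
    base$fisher_p <- fish
    base$significant <- if (is.na(fish)) NA else
      classify_module(zp$z, fish, p_perm = zp$p_perm, alpha = alpha,
                      fisher_max = fisher_max)
    base
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$z, out$module, na.last = TRUE), ]
  rownames(out) <- NULL
  class(out) <- c("module_activation", "data.frame")
  attr(out, "alpha") <- alpha
  attr(out, "fisher_max") <- fisher_max
  out
}
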
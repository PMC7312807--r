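# Synthetic expression experiments with implanted, known module effects.
# The generator mirrors the study design the scoring stage expects:
# two cohorts of n = 5 samples, thousands of genes with Gaussian noise on
# the log scale, and a panel of 8-11 injury modules of which some carry
# an implanted log fold-change effect.

#' Describe one module for the simulator
#'
#' @param name Module name.
#' @param size Number of member genes (ignored when `genes` is given).
#' @param effect Implanted log fold-change magnitude (natural-log units);
#'   0 means a null module.
#' @param direction_mix Fraction of member genes shifted up (the rest are
#'   shifted down). Default 0.5 so the sign-invariant AAFC score is
#'   exercised with balanced directions.
#' @param class Injury class label or NA.
#' @param genes Optional explicit member gene IDs.
#' @return A list describing the module, for [simulation_config()].
#' @export
module_spec <- function(name, size, effect = 0, direction_mix = 0.5,
                        class = NA_character_, genes = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (is.null(genes) && (!is.numeric(size) || size < 1L))
    stop(sprintf("module '%s': size must be a positive count", name),
         call. = FALSE)
  if (direction_mix < 0 || direction_mix > 1)
    stop("direction_mix must lie in [0, 1]", call. = FALSE)
  list(name = name, size = if (is.null(genes)) as.integer(size)
       else length(genes),
       effect = as.numeric(effect), direction_mix = direction_mix,
       class = class, genes = genes)
}

#' Configure a synthetic expression experiment
#'
#' @param n_genes Number of genes.
#' @param n_per_cohort Samples per cohort (default 5, the study design).
#' @param noise_sd Standard deviation of log-expression noise (> 0).
#' @param baseline_mean Baseline log-expression level.
#' @param modules List of [module_spec()] entries.
#' @param seed Integer seed; identical configs and seeds give identical
#'   output.
#' @param disjoint Require module memberships to be disjoint.
#' @param gene_prefix Prefix for synthetic gene symbols ("G000001", ...),
#'   e.g. "HS_" / "RN_" for per-system identifiers.
#' @return An object of class `simulation_config`.
#' @examples
#' cfg <- simulation_config(1000, modules = list(
#'   module_spec("Fibrogenesis", 50, effect = 1, class = "inflammation")),
#'   seed = 7)
#' @export
simulation_config <- function(n_genes, n_per_cohort = 5L, noise_sd = 0.5,
                              baseline_mean = 5, modules = list(),
                              seed = 1L, disjoint = TRUE,
                              gene_prefix = "") {
  n_genes <- as.integer(n_genes)
  n_per_cohort <- as.integer(n_per_cohort)
  if (n_genes < 1L) stop("n_genes must be positive", call. = FALSE)
  if (n_per_cohort < 2L) stop("n_per_cohort must be >= 2", call. = FALSE)
  if (!is.numeric(noise_sd) || noise_sd <= 0)
    stop("noise_sd must be > 0", call. = FALSE)
  sizes <- vapply(modules, `[[`, numeric(1), "size")
  if (any(sizes > n_genes))
    stop("module size exceeds n_genes", call. = FALSE)
  if (disjoint && sum(sizes) > n_genes)
    stop("module sizes sum to more than n_genes under disjointness",
         call. = FALSE)
  structure(
    list(n_genes = n_genes, n_per_cohort = n_per_cohort,
         noise_sd = noise_sd, baseline_mean = baseline_mean,
         modules = modules, seed = as.integer(seed),
         disjoint = disjoint, gene_prefix = gene_prefix),
    class = "simulation_config"
  )
}

#' Generate an expression experiment with known ground truth
#'
#' Control samples are drawn as `baseline_mean` plus Gaussian noise;
#' treatment samples of genes inside a module with implanted effect `e`
#' have their mean shifted by `+e` or `-e` according to the module's
#' `direction_mix`. Genes outside modules are pure null.
#'
#' @param config A [simulation_config()].
#' @return A list with elements `experiment` (an
#'   [expression_experiment()]) and `truth` (list with `gene_effects`, a
#'   data.frame of gene_id/module/effect for implanted genes, and
#'   `module_effects`, a data.frame of module/class/effect/size).
#' @examples
#' sim <- generate_experiment(simulation_config(200, seed = 1))
#' dim(sim$experiment$values)
#' @export
generate_experiment <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, {
    n <- config$n_genes
    m <- config$n_per_cohort
    gene_ids <- sprintf("%sG%06d", config$gene_prefix, seq_len(n))
    sample_ids <- c(sprintf("TRT_%d", seq_len(m)),
                    sprintf("CTL_%d", seq_len(m)))
    cohort <- rep(c("treatment", "control"), each = m)

    members <- assign_memberships(config, gene_ids)
    shift <- numeric(n)
    gene_rows <- list()
    for (mod in seq_along(config$modules)) {
      spec <- config$modules[[mod]]
      idx <- members[[mod]]
      if (spec$effect != 0) {
        up <- runif(length(idx)) < spec$direction_mix
        eff <- ifelse(up, spec$effect, -spec$effect)
        shift[idx] <- shift[idx] + eff
        gene_rows[[length(gene_rows) + 1L]] <- data.frame(
          gene_id = gene_ids[idx], module = spec$name, effect = eff,
          stringsAsFactors = FALSE)
      } else {
        gene_rows[[length(gene_rows) + 1L]] <- data.frame(
          gene_id = gene_ids[idx], module = spec$name, effect = 0,
          stringsAsFactors = FALSE)
      }
    }
    values <- matrix(rnorm(n * 2L * m, mean = config$baseline_mean,
                           sd = config$noise_sd),
                     nrow = n, ncol = 2L * m,
                     dimnames = list(gene_ids, sample_ids))
    values[, seq_len(m)] <- values[, seq_len(m)] + shift

    truth <- list(
      gene_effects = if (length(gene_rows)) do.call(rbind, gene_rows)
        else data.frame(gene_id = character(), module = character(),
                        effect = numeric(), stringsAsFactors = FALSE),
      module_effects = data.frame(
        module = vapply(config$modules, `[[`, character(1), "name"),
        class = vapply(config$modules, function(s)
          if (is.null(s$class)) NA_character_ else as.character(s$class),
          character(1)),
        effect = vapply(config$modules, `[[`, numeric(1), "effect"),
        size = vapply(config$modules, function(s) length(s$genes %||%
          integer(s$size)), numeric(1)),
        stringsAsFactors = FALSE),
      members = lapply(members, function(i) gene_ids[i])
    )
    names(truth$members) <- truth$module_effects$module
    list(
      experiment = expression_experiment(values, cohort,
                                         meta = list(synthetic = TRUE)),
      truth = truth
    )
  })
}

# Resolve module memberships to gene indices; explicit sets are honoured,
# remaining modules get random disjoint (or independent) draws.
assign_memberships <- function(config, gene_ids) {
  n <- config$n_genes
  explicit <- lapply(config$modules, function(s) {
    if (is.null(s$genes)) return(NULL)
    idx <- match(s$genes, gene_ids)
    if (anyNA(idx))
      stop(sprintf("module '%s' names genes outside the experiment",
                   s$name), call. = FALSE)
    idx
  })
  taken <- unlist(explicit)
  if (config$disjoint && anyDuplicated(taken))
    stop("module memberships overlap but disjoint sets were requested",
         call. = FALSE)
  free <- setdiff(seq_len(n), taken)
  members <- vector("list", length(config$modules))
  for (i in seq_along(config$modules)) {
    if (!is.null(explicit[[i]])) {
      members[[i]] <- explicit[[i]]
    } else {
      size <- config$modules[[i]]$size
      pool <- if (config$disjoint) free else seq_len(n)
      if (size > length(pool))
        stop("not enough free genes for module '",
             config$modules[[i]]$name, "'", call. = FALSE)
      pick <- sample(pool, size)
      members[[i]] <- pick
      if (config$disjoint) free <- setdiff(free, pick)
    }
  }
  members
}

#' Generate a synthetic module collection
#'
#' Draws `n_modules` gene sets over a universe of `n_genes` synthetic
#' symbols. When `organ` is given, module names and injury-class labels
#' follow the canonical liver (11) or kidney (8) panel of
#' [injury_module_panel()].
#'
#' @param n_modules Number of modules.
#' @param sizes Integer vector of set sizes (recycled).
#' @param n_genes Universe size.
#' @param seed Integer seed.
#' @param organ Optional `"liver"` or `"kidney"` for fixture names.
#' @param overlap Allow sets to overlap (default disjoint).
#' @param gene_prefix Prefix for gene symbols.
#' @return A [module_collection()].
#' @examples
#' generate_module_collection(11, 30, 2000, seed = 1, organ = "liver")
#' @export
generate_module_collection <- function(n_modules, sizes, n_genes,
                                       seed = 1L, organ = NULL,
                                       overlap = FALSE,
                                       gene_prefix = "") {
  n_modules <- as.integer(n_modules)
  if (n_modules < 1L) stop("n_modules must be positive", call. = FALSE)
  sizes <- rep_len(as.integer(sizes), n_modules)
  if (any(sizes < 1L))
    stop("module sizes must be positive (empty sets rejected)",
         call. = FALSE)
  if (any(sizes > n_genes))
    stop("module size exceeds the gene universe", call. = FALSE)
  if (!overlap && sum(sizes) > n_genes)
    stop("disjoint sizes exceed the gene universe", call. = FALSE)
  if (!is.null(organ)) {
    panel <- injury_module_panel(organ)
    if (n_modules > nrow(panel))
      stop(sprintf("the %s panel has only %d module names", organ,
                   nrow(panel)), call. = FALSE)
    nms <- panel$module[seq_len(n_modules)]
    cls <- panel$class[seq_len(n_modules)]
  } else {
    nms <- sprintf("M%02d", seq_len(n_modules))
    cls <- rep(NA_character_, n_modules)
  }
  gene_ids <- sprintf("%sG%06d", gene_prefix, seq_len(n_genes))
  with_seed(seed, {
    free <- seq_len(n_genes)
    mods <- vector("list", n_modules)
    for (i in seq_len(n_modules)) {
      pool <- if (overlap) seq_len(n_genes) else free
      pick <- sample(pool, sizes[i])
      if (!overlap) free <- setdiff(free, pick)
      mods[[i]] <- list(name = nms[i], class = cls[i],
                        genes = gene_ids[pick])
    }
    module_collection(mods)
  })
}

#' Configure a multi-system simulation
#'
#' @param systems Character vector of at least two system labels, e.g.
#'   `c("human_ivt", "rat_ivv")`.
#' @param shared_effect_correlation Value in `[-1, 1]`: the expected
#'   correlation between the implanted per-module effect vectors of any
#'   two systems (1 = identical injuries, 0 = independent).
#' @param ortholog_fraction Fraction of genes with a cross-system
#'   ortholog, in `(0, 1]`.
#' @param base A [simulation_config()] shared by all systems; its
#'   modules' `effect` fields set the effect scale per module.
#' @return An object of class `multi_system_config`.
#' @export
multi_system_config <- function(systems, shared_effect_correlation,
                                ortholog_fraction, base) {
  systems <- as.character(systems)
  if (length(systems) < 2L)
    stop("at least 2 systems are required", call. = FALSE)
  if (anyDuplicated(systems))
    stop("system labels must be unique", call. = FALSE)
  rho <- shared_effect_correlation
  if (!is.numeric(rho) || rho < -1 || rho > 1)
    stop("shared_effect_correlation must lie in [-1, 1]", call. = FALSE)
  if (!is.numeric(ortholog_fraction) || ortholog_fraction <= 0 ||
      ortholog_fraction > 1)
    stop("ortholog_fraction must lie in (0, 1]", call. = FALSE)
  stopifnot(inherits(base, "simulation_config"))
  structure(
    list(systems = systems, shared_effect_correlation = rho,
         ortholog_fraction = ortholog_fraction, base = base),
    class = "multi_system_config"
  )
}

#' Generate ortholog-linked experiments for several systems
#'
#' Each module's implanted signed effect in system s is
#' `scale * (rho * z + sqrt(1 - rho^2) * e_s)` with `z` shared across
#' systems and `e_s` idiosyncratic standard-normal loadings, so the
#' implanted effect vectors of any two systems have expected correlation
#' `rho` (`shared_effect_correlation`). Module memberships are linked
#' through gene position: gene i of every system is the same underlying
#' gene, carried under a per-system identifier prefix, and the ortholog
#' map covers `ortholog_fraction` of positions.
#'
#' @param config A [multi_system_config()].
#' @return A list with `experiments` (named list of per-system
#'   generate_experiment results), `collections` (per-system
#'   [module_collection()] under that system's gene IDs),
#'   `ortholog_maps` (named list, one data.frame of
#'   source_gene/target_gene per unordered system pair, names
#'   `"A->B"`), and `truth` (`effects`: modules x systems matrix of
#'   implanted signed effects; `loadings` likewise).
#' @examples
#' base <- simulation_config(500, modules = list(
#'   module_spec("M1", 20, effect = 1), module_spec("M2", 20, effect = 1)),
#'   seed = 3)
#' ms <- generate_multi_system(
#'   multi_system_config(c("HS", "RN"), 1, 0.8, base))
#' nrow(ms$ortholog_maps[["HS->RN"]])
#' @export
generate_multi_system <- function(config) {
  stopifnot(inherits(config, "multi_system_config"))
  base <- config$base
  k <- length(base$modules)
  if (k == 0L)
    stop("the base config must define at least one module", call. = FALSE)
  rho <- config$shared_effect_correlation
  systems <- config$systems
  prefixes <- paste0(gsub("[^A-Za-z0-9]", "", toupper(systems)), "_")
  if (anyDuplicated(prefixes))
    stop("system labels collapse to identical gene prefixes", call. = FALSE)

  with_seed(base$seed, {
    scale <- vapply(base$modules, `[[`, numeric(1), "effect")
    z_shared <- rnorm(k)
    loadings <- sapply(systems, function(s) {
      rho * z_shared + sqrt(max(0, 1 - rho^2)) * rnorm(k)
    })
    loadings <- matrix(loadings, nrow = k,
                       dimnames = list(
                         vapply(base$modules, `[[`, character(1), "name"),
                         systems))
    effects <- loadings * scale

    # shared membership by gene position, reused across systems
    member_idx <- assign_memberships(
      simulation_config(base$n_genes, base$n_per_cohort, base$noise_sd,
                        base$baseline_mean, base$modules,
                        seed = base$seed, disjoint = base$disjoint),
      sprintf("G%06d", seq_len(base$n_genes)))
    seeds <- sample.int(2147483646L, length(systems))

    experiments <- vector("list", length(systems))
    collections <- vector("list", length(systems))
    for (si in seq_along(systems)) {
      gene_ids <- sprintf("%sG%06d", prefixes[si], seq_len(base$n_genes))
      mods <- lapply(seq_len(k), function(j) {
        spec <- base$modules[[j]]
        module_spec(spec$name, length(member_idx[[j]]),
                    effect = effects[j, si],
                    direction_mix = spec$direction_mix,
                    class = spec$class,
                    genes = gene_ids[member_idx[[j]]])
      })
      cfg <- simulation_config(base$n_genes, base$n_per_cohort,
                               base$noise_sd, base$baseline_mean,
                               modules = mods, seed = seeds[si],
                               disjoint = base$disjoint,
                               gene_prefix = prefixes[si])
      experiments[[si]] <- generate_experiment(cfg)
      collections[[si]] <- module_collection(mods)
    }
    names(experiments) <- names(collections) <- systems

    n_orth <- round(config$ortholog_fraction * base$n_genes)
    orth_idx <- sort(sample.int(base$n_genes, n_orth))
    pairs <- utils::combn(seq_along(systems), 2L, simplify = FALSE)
    ortholog_maps <- lapply(pairs, function(p) {
      data.frame(
        source_gene = sprintf("%sG%06d", prefixes[p[1]], orth_idx),
        target_gene = sprintf("%sG%06d", prefixes[p[2]], orth_idx),
        stringsAsFactors = FALSE)
    })
    names(ortholog_maps) <- vapply(pairs, function(p)
      paste0(systems[p[1]], "->", systems[p[2]]), character(1))

    list(experiments = experiments, collections = collections,
         ortholog_maps = ortholog_maps,
         truth = list(effects = effects, loadings = loadings))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's stream afterwards.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic 31-bit substream seed from a root seed and a name, so
# per-module results do not depend on module order.
string_seed <- function(seed, name) {
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 31 + ch) %% 2147483629
  as.integer((as.numeric(seed) + h) %% 2147483629)
}
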
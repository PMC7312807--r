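# Config-driven orchestration of the simulate -> fc -> deg -> score ->
# compare stages, with stable on-disk artifacts and a reproducibility
# manifest (config hash + per-file checksums + seeds).

PIPELINE_STAGES <- c("simulate", "fc", "deg", "score", "compare")

#' Build a pipeline run configuration
#'
#' @param out_dir Output directory (created if missing).
#' @param stages Stages to run, in dependency order; any subset of
#'   `simulate`, `fc`, `deg`, `score`, `compare`.
#' @param seed Integer seed; mandatory whenever a stochastic stage
#'   (`simulate`, `score`) is requested.
#' @param systems System labels. One label runs a single-system
#'   analysis; two or more run an ortholog-linked multi-system scenario
#'   (required by `compare`).
#' @param simulate Named list of generator settings: `n_genes`,
#'   `n_per_cohort`, `noise_sd`, `baseline_mean`, `organ` (fixture panel
#'   for module names), `n_modules`, `module_size`, `effects` (named
#'   vector of implanted log fold-change magnitudes per module),
#'   `shared_effect_correlation`, `ortholog_fraction`.
#' @param inputs Named list of pre-existing input paths per system when
#'   `simulate` is not run: each system maps to
#'   `list(matrix =, cohorts =)`; plus `modules` (GMT path) and
#'   optionally `orthologs` (TSV path).
#' @param deg List with `q_max`, `effect_min` (see [deg_criteria()]).
#' @param score List with `B`, `alpha`, `fisher_max`, `min_coverage`.
#' @param ortholog_policy `"one_to_one"` or `"any"` for the compare
#'   stage.
#' @param verbose Log stage progress to stderr.
#' @return An object of class `run_config`.
#' @export
run_config <- function(out_dir, stages = PIPELINE_STAGES, seed = NULL,
                       systems = "system1",
                       simulate = list(), inputs = list(),
                       deg = list(), score = list(),
                       ortholog_policy = "one_to_one",
                       verbose = FALSE) {
  stages <- match.arg(stages, PIPELINE_STAGES, several.ok = TRUE)
  stages <- PIPELINE_STAGES[PIPELINE_STAGES %in% stages]
  if (any(c("simulate", "score") %in% stages) && is.null(seed))
    stop("a seed is mandatory for the stochastic stages", call. = FALSE)
  sim_defaults <- list(n_genes = 2000L, n_per_cohort = 5L, noise_sd = 0.5,
                       baseline_mean = 5, organ = "liver",
                       n_modules = 11L, module_size = 30L,
                       effects = NULL,
                       shared_effect_correlation = 1,
                       ortholog_fraction = 0.9)
  deg_defaults <- list(q_max = 0.05, effect_min = 0.41)
  score_defaults <- list(B = 10000L, alpha = 0.05, fisher_max = 0.01,
                         min_coverage = 0.3)
  structure(
    list(out_dir = out_dir, stages = stages,
         seed = if (is.null(seed)) NULL else as.integer(seed),
         systems = as.character(systems),
         simulate = utils::modifyList(sim_defaults, simulate),
         inputs = inputs,
         deg = utils::modifyList(deg_defaults, deg),
         score = utils::modifyList(score_defaults, score),
         ortholog_policy = ortholog_policy,
         verbose = isTRUE(verbose)),
    class = "run_config"
  )
}

#' Read a run configuration from YAML or JSON
#'
#' @param path `.yaml`/`.yml` or `.json` file whose keys mirror the
#'   [run_config()] arguments.
#' @param ... Overrides applied on top of the file (CLI flags).
#' @return A `run_config`.
#' @export
read_run_config <- function(path, ...) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  overrides <- list(...)
  raw[names(overrides)] <- overrides
  do.call(run_config, raw)
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order, validating that
#' every input a stage needs exists before any computation starts.
#' Stage outputs are laid out under `out_dir` (one subdirectory per
#' system) and a manifest with the config hash, per-file MD5 checksums
#' and the seeds used is written to `manifest.json`. When a manifest
#' from a previous run is present with the same config hash, stages
#' whose recorded outputs are unchanged on disk are skipped; a failing
#' stage halts downstream stages but leaves upstream outputs in place.
#'
#' @param config A [run_config()] or a path to a YAML/JSON config.
#' @return The manifest, invisibly (class `run_manifest`).
#' @examples
#' \donttest{
#' cfg <- run_config(tempfile("run"), seed = 1, systems = "rat_ivv",
#'                   simulate = list(n_genes = 300, n_modules = 4,
#'                                   module_size = 15,
#'                                   effects = c(Fibrogenesis = 1)),
#'                   score = list(B = 200))
#' manifest <- run_pipeline(cfg)
#' }
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  validate_stage_inputs(config)

  hash <- config_hash(config)
  manifest_path <- file.path(config$out_dir, "manifest.json")
  previous <- if (file.exists(manifest_path))
    tryCatch(jsonlite::read_json(manifest_path, simplifyVector = TRUE),
             error = function(e) NULL) else NULL
  if (!is.null(previous) && !identical(previous$config_hash, hash))
    previous <- NULL

  manifest <- list(
    package = "injurymod",
    version = as.character(utils::packageVersion("injurymod")),
    config_hash = hash,
    seed = config$seed,
    generated = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    stages = list()
  )
  for (stage in config$stages) {
    skip <- stage_up_to_date(previous, stage)
    if (skip) {
      log_stage(config, stage, "up to date, skipped")
      manifest$stages[[stage]] <- previous$stages[[stage]]
      next
    }
    log_stage(config, stage, "running")
    files <- switch(stage,
      simulate = stage_simulate(config),
      fc       = stage_fc(config),
      deg      = stage_deg(config),
      score    = stage_score(config),
      compare  = stage_compare(config))
    manifest$stages[[stage]] <- list(
      files = files,
      md5 = unname(tools::md5sum(files)),
      seed = if (stage %in% c("simulate", "score")) config$seed else NULL)
  }
  class(manifest) <- "run_manifest"
  jsonlite::write_json(unclass(manifest), manifest_path,
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(manifest)
}

log_stage <- function(config, stage, msg) {
  if (config$verbose)
    message(sprintf("[injurymod] %s stage %s: %s",
                    format(Sys.time(), "%H:%M:%S"), stage, msg))
}

stage_up_to_date <- function(previous, stage) {
  if (is.null(previous) || is.null(previous$stages[[stage]])) return(FALSE)
  rec <- previous$stages[[stage]]
  files <- unlist(rec$files)
  if (!length(files) || !all(file.exists(files))) return(FALSE)
  identical(unname(unlist(rec$md5)), unname(tools::md5sum(files)))
}

# Fail before any computation if a requested stage lacks its inputs.
validate_stage_inputs <- function(config) {
  simulated <- "simulate" %in% config$stages
  sysdirs <- file.path(config$out_dir, config$systems)
  for (stage in setdiff(config$stages, "simulate")) {
    for (s in seq_along(config$systems)) {
      sys <- config$systems[s]
      need <- switch(stage,
        fc = if (!simulated) {
          inp <- config$inputs[[sys]]
          if (is.null(inp$matrix) || is.null(inp$cohorts))
            stop(sprintf(
              "stage 'fc' needs inputs$%s$matrix and $cohorts (or the simulate stage)",
              sys), call. = FALSE)
          c(inp$matrix, inp$cohorts)
        },
        score = if (!simulated && is.null(config$inputs$modules))
          stop("stage 'score' needs inputs$modules (a GMT file) or the simulate stage",
               call. = FALSE)
        else if (!simulated) config$inputs$modules,
        NULL)
      for (p in need)
        if (!file.exists(p))
          stop(sprintf("stage '%s': input file not found: %s", stage, p),
               call. = FALSE)
    }
  }
  if ("compare" %in% config$stages && length(config$systems) < 2L)
    stop("stage 'compare' needs at least 2 systems", call. = FALSE)
  invisible(TRUE)
}

sys_dir <- function(config, sys) {
  d <- file.path(config$out_dir, sys)
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  d
}

build_module_specs <- function(sim) {
  panel <- if (!is.null(sim$organ)) injury_module_panel(sim$organ) else
    data.frame(module = sprintf("M%02d", seq_len(sim$n_modules)),
               class = NA_character_, stringsAsFactors = FALSE)
  n <- min(sim$n_modules, nrow(panel))
  lapply(seq_len(n), function(i) {
    eff <- 0
    if (!is.null(sim$effects) && panel$module[i] %in% names(sim$effects))
      eff <- sim$effects[[panel$module[i]]]
    module_spec(panel$module[i], sim$module_size, effect = eff,
                class = panel$class[i])
  })
}

stage_simulate <- function(config) {
  sim <- config$simulate
  specs <- build_module_specs(sim)
  base <- simulation_config(sim$n_genes, sim$n_per_cohort, sim$noise_sd,
                            sim$baseline_mean, modules = specs,
                            seed = config$seed)
  files <- character(0)
  if (length(config$systems) == 1L) {
    out <- generate_experiment(base)
    d <- sys_dir(config, config$systems)
    files <- c(files, write_experiment(out$experiment,
                                       file.path(d, "matrix.tsv"),
                                       file.path(d, "cohorts.tsv")))
    coll <- module_collection(lapply(names(out$truth$members), function(nm)
      list(name = nm,
           class = out$truth$module_effects$class[
             out$truth$module_effects$module == nm],
           genes = out$truth$members[[nm]])))
    files <- c(files, write_gmt(coll, file.path(d, "modules.gmt")))
    truth_path <- file.path(d, "truth.json")
    jsonlite::write_json(out$truth[c("gene_effects", "module_effects")],
                         truth_path, auto_unbox = TRUE, digits = NA)
    files <- c(files, truth_path)
  } else {
    ms <- generate_multi_system(multi_system_config(
      config$systems, sim$shared_effect_correlation,
      sim$ortholog_fraction, base))
    for (sys in config$systems) {
      d <- sys_dir(config, sys)
      files <- c(files, write_experiment(ms$experiments[[sys]]$experiment,
                                         file.path(d, "matrix.tsv"),
                                         file.path(d, "cohorts.tsv")))
      files <- c(files, write_gmt(ms$collections[[sys]],
                                  file.path(d, "modules.gmt")))
    }
    for (nm in names(ms$ortholog_maps)) {
      p <- file.path(config$out_dir,
                     paste0("orthologs_", gsub("->", "_to_", nm, fixed = TRUE),
                            ".tsv"))
      files <- c(files, write_ortholog_map(ms$ortholog_maps[[nm]], p))
    }
    truth_path <- file.path(config$out_dir, "truth.json")
    jsonlite::write_json(
      list(effects = as.data.frame(ms$truth$effects)),
      truth_path, auto_unbox = TRUE, digits = NA)
    files <- c(files, truth_path)
  }
  unname(files)
}

pipeline_inputs <- function(config, sys) {
  d <- file.path(config$out_dir, sys)
  inp <- config$inputs[[sys]]
  list(matrix = inp$matrix %||% file.path(d, "matrix.tsv"),
       cohorts = inp$cohorts %||% file.path(d, "cohorts.tsv"),
       modules = config$inputs$modules %||% file.path(d, "modules.gmt"))
}

stage_fc <- function(config) {
  unname(unlist(lapply(config$systems, function(sys) {
    inp <- pipeline_inputs(config, sys)
    exp <- load_experiment(inp$matrix, inp$cohorts,
                           meta = list(system = sys))
    write_fc_table(compute_fc(exp),
                   file.path(sys_dir(config, sys), "fc.tsv"))
  })))
}

stage_deg <- function(config) {
  crit <- deg_criteria(config$deg$q_max, config$deg$effect_min)
  unname(unlist(lapply(config$systems, function(sys) {
    d <- sys_dir(config, sys)
    degs <- call_degs(read_fc_table(file.path(d, "fc.tsv")), crit)
    write_gene_list(degs$gene_id, file.path(d, "degs.txt"))
  })))
}

stage_score <- function(config) {
  sc <- config$score
  unname(unlist(lapply(config$systems, function(sys) {
    d <- sys_dir(config, sys)
    inp <- pipeline_inputs(config, sys)
    scores <- score_all_modules(
      read_fc_table(file.path(d, "fc.tsv")), read_gmt(inp$modules),
      B = sc$B, seed = config$seed, alpha = sc$alpha,
      fisher_max = sc$fisher_max, min_coverage = sc$min_coverage)
    tsv <- write_activation_table(scores, file.path(d, "activation.tsv"))
    json <- file.path(d, "activation.json")
    jsonlite::write_json(as.data.frame(scores), json, auto_unbox = TRUE,
                         digits = NA)
    c(tsv, json)
  })))
}

stage_compare <- function(config) {
  systems <- config$systems
  files <- character(0)
  scores <- lapply(systems, function(sys) {
    tab <- utils::read.delim(
      file.path(config$out_dir, sys, "activation.tsv"),
      stringsAsFactors = FALSE)
    tab[order(tab$module), ]
  })
  names(scores) <- systems

  # pairwise Pearson correlation of module activation vectors
  pairs <- utils::combn(systems, 2L, simplify = FALSE)
  cors <- do.call(rbind, lapply(pairs, function(p) {
    a <- activation_vector(p[1], "run", scores[[p[1]]]$module,
                           scores[[p[1]]]$z)
    b <- activation_vector(p[2], "run", scores[[p[2]]]$module,
                           scores[[p[2]]]$z)
    ct <- correlate_activation(a, b)
    data.frame(system_a = p[1], system_b = p[2], r = ct$r, p = ct$p,
               n_modules = ct$n, stringsAsFactors = FALSE)
  }))
  cor_path <- file.path(config$out_dir, "correlation.tsv")
  utils::write.table(cors, cor_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files <- c(files, cor_path)

  # ortholog-mapped DEG overlap for each pair with a map on disk
  overlaps <- list()
  for (p in pairs) {
    map_path <- file.path(config$out_dir,
                          paste0("orthologs_", p[1], "_to_", p[2], ".tsv"))
    if (is.null(config$inputs$orthologs) && !file.exists(map_path)) next
    map <- read_ortholog_map(config$inputs$orthologs %||% map_path)
    deg_a <- read_gene_list(file.path(config$out_dir, p[1], "degs.txt"))
    deg_b <- read_gene_list(file.path(config$out_dir, p[2], "degs.txt"))
    fc_b <- read_fc_table(file.path(config$out_dir, p[2], "fc.tsv"))
    mapped <- map_orthologs(deg_a, map, policy = config$ortholog_policy)
    rep <- overlap_with_expectation(
      stats::setNames(list(mapped$mapped, deg_b), p),
      universe_size = nrow(fc_b))
    overlaps[[paste(p, collapse = "_vs_")]] <- list(
      n_unmapped = mapped$n_unmapped, n_collapsed = mapped$n_collapsed,
      observed = as.list(rep$observed), expected = as.list(rep$expected),
      universe_size = rep$universe_size)
  }
  if (length(overlaps)) {
    ov_path <- file.path(config$out_dir, "overlap.json")
    jsonlite::write_json(overlaps, ov_path, auto_unbox = TRUE, digits = NA)
    files <- c(files, ov_path)
  }

  # condition-level PCA on the module activation matrix
  zmat <- do.call(rbind, lapply(scores, function(s) s$z))
  rownames(zmat) <- systems
  colnames(zmat) <- scores[[1]]$module
  if (nrow(zmat) >= 2L && ncol(zmat) >= 2L && all(is.finite(zmat))) {
    pca <- pca_conditions(zmat, mode = "module")
    pca_path <- file.path(config$out_dir, "pca.tsv")
    coords <- data.frame(condition = rownames(pca$coordinates),
                         pca$coordinates, check.names = FALSE)
    utils::write.table(coords, pca_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- c(files, pca_path)
  }
  files
}

# Stable hash of the configuration (seed and stage settings included).
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  cfg <- unclass(config)
  cfg$out_dir <- NULL   # relocating a run must not force a rerun
  cfg$verbose <- NULL
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  unname(tools::md5sum(tmp))
}

#' Write report files for activation and cross-system results
#'
#' Emits the activation table as TSV and JSON (significance encoded as
#' a boolean column) and, when comparison results are supplied, the
#' correlation table and overlap report. The comparison block is simply
#' omitted when absent.
#'
#' @param scores A `module_activation` table.
#' @param dir Output directory.
#' @param correlations Optional data.frame of pairwise correlations.
#' @param overlap Optional `overlap_report`.
#' @return Character vector of files written.
#' @export
write_report <- function(scores, dir, correlations = NULL,
                         overlap = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- write_activation_table(scores, file.path(dir, "activation.tsv"))
  json <- file.path(dir, "activation.json")
  jsonlite::write_json(as.data.frame(scores), json, auto_unbox = TRUE,
                       digits = NA)
  files <- c(files, json)
  if (!is.null(correlations)) {
    p <- file.path(dir, "correlation.tsv")
    utils::write.table(correlations, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- c(files, p)
  }
  if (!is.null(overlap)) {
    p <- file.path(dir, "overlap.json")
    jsonlite::write_json(
      list(observed = as.list(overlap$observed),
           expected = as.list(overlap$expected),
           universe_size = overlap$universe_size),
      p, auto_unbox = TRUE, digits = NA)
    files <- c(files, p)
  }
  files
}
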
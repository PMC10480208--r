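#' Pipeline configuration
#'
#' One configuration object drives [run_pipeline()]: stage toggles, a
#' per-stage parameter block mirroring each stage's function arguments, a
#' global seed (deterministically spawning per-stage sub-seeds, so a
#' stage's outputs do not depend on which other stages are enabled), and
#' the output directory.
#'
#' @param out output directory.
#' @param seed global integer seed.
#' @param stages character vector of enabled stages, in any order; the
#'   pipeline runs them in dependency order. Known stages: `simulate`,
#'   `cohesion`, `network`, `screen`, `mcn`, `modules`, `interactions`.
#' @param simulate,cohesion,network,screen,mcn,modules,interactions named
#'   lists of parameter overrides for the corresponding stage functions.
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(out = tempfile("compostcoop_run_"), seed = 1,
                            stages = c("simulate", "cohesion", "network",
                                       "screen", "mcn", "modules",
                                       "interactions"),
                            simulate = list(), cohesion = list(),
                            network = list(), screen = list(), mcn = list(),
                            modules = list(), interactions = list()) {
  known <- c("simulate", "cohesion", "network", "screen", "mcn", "modules",
             "interactions")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  structure(list(out = out, seed = as.integer(seed), stages = stages,
                 simulate = simulate, cohesion = cohesion, network = network,
                 screen = screen, mcn = mcn, modules = modules,
                 interactions = interactions),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file whose keys mirror [pipeline_config()] arguments.
#' @return a `"pipeline_config"`.
#' @export
read_pipeline_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the yaml package is required to read YAML configurations")
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Run the composting analysis pipeline end to end
#'
#' Executes the enabled stages in dependency order (simulate, cohesion,
#' network, screen, mcn, modules, interactions), writing each stage's
#' tables under `config$out` and a machine-readable `manifest.json`
#' (package version, global seed, per-stage sub-seeds and parameters, and
#' an md5 checksum of every file written). Every table carries a `#`
#' provenance header with the seed and parameter hash. Stages that need an
#' upstream product (e.g. `cohesion` without `simulate` and without an
#' explicit input) raise a dependency error naming the stage.
#'
#' @param config a `"pipeline_config"` (or YAML path).
#' @param table,metadata optional externally supplied abundance table and
#'   metadata (used when the `simulate` stage is disabled).
#' @return invisibly, a list of in-memory stage results plus the run
#'   directory.
#' @export
run_pipeline <- function(config = pipeline_config(), table = NULL,
                         metadata = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
  res <- list(out = config$out)
  written <- character(0)
  prov <- function(stage, params) paste0(
    "seed=", stage_seed(config$seed, stage), " stage=", stage,
    " params_md5=", digest_params(params))
  emit <- function(x, file, stage, params, id_name = "id") {
    p <- file.path(config$out, file)
    write_table(x, p, id_name = id_name, provenance = prov(stage, params))
    written <<- c(written, p)
    p
  }
  need <- function(obj, stage, what)
    if (is.null(obj)) stop("dependency error in stage '", stage,
                           "': missing upstream ", what)

  if ("simulate" %in% config$stages) {
    sim_args <- config$simulate
    sim_args$seed <- stage_seed(config$seed, "simulate")
    sim <- simulate_composting(do.call(simulation_config, sim_args))
    table <- sim$table; metadata <- sim$metadata
    res$simulate <- sim
    emit(unclass(sim$table), "abundance.tsv", "simulate", sim_args,
         id_name = "sample_id")
    emit(sim$metadata, "metadata.tsv", "simulate", sim_args,
         id_name = "sample_id")
    emit(sim$traits, "traits.tsv", "simulate", sim_args, id_name = "taxon_id")
    write_ground_truth(sim$truth, file.path(config$out, "ground_truth.json"))
    written <- c(written, file.path(config$out, "ground_truth.json"))

    cc_args <- config$interactions[intersect(names(config$interactions),
                                             c("n_pairs", "type_mix",
                                               "effect_size", "noise_sd",
                                               "replicates"))]
    cc_args$seed <- stage_seed(config$seed, "coculture")
    cc <- do.call(simulate_coculture, cc_args)
    res$coculture <- cc
    write_coculture(cc$records, file.path(config$out, "coculture.csv"))
    written <- c(written, file.path(config$out, "coculture.csv"))

    gn <- simulate_genomes(seed = stage_seed(config$seed, "genomes"))
    res$genomes <- gn
    emit(gn$annotations, "genome_annotations.tsv", "simulate", list(),
         id_name = "row")
  }

  if ("cohesion" %in% config$stages) {
    need(table, "cohesion", "abundance table")
    args <- utils::modifyList(list(n_iters = 200, method = "pearson"),
                              config$cohesion)
    coh <- cohesion_analysis(table, n_iters = args$n_iters,
                             method = args$method,
                             seed = stage_seed(config$seed, "cohesion"))
    res$cohesion <- coh
    emit(data.frame(pos = coh$pos_connectedness, neg = coh$neg_connectedness,
                    row.names = names(coh$pos_connectedness)),
         "connectedness.tsv", "cohesion", args, id_name = "taxon_id")
    emit(data.frame(pos_cohesion = coh$pos_cohesion,
                    neg_cohesion = coh$neg_cohesion,
                    row.names = names(coh$pos_cohesion)),
         "cohesion.tsv", "cohesion", args, id_name = "sample_id")
    emit(coh$corrected_corr, "corrected_correlations.tsv", "cohesion", args,
         id_name = "taxon_id")
    if (!is.null(metadata)) {
      assoc <- cohesion_temperature_association(coh$pos_cohesion, metadata)
      res$cohesion_temperature <- assoc
    }
  }

  if ("network" %in% config$stages) {
    need(table, "network", "abundance table")
    need(metadata, "network", "sample metadata")
    args <- utils::modifyList(list(s_min = 0.30, s_max = 0.99, step = 0.01,
                                   n_random = 100, n_swaps_per_edge = 10),
                              config$network)
    nw <- build_cooccurrence_network(table, metadata, s_min = args$s_min,
                                     s_max = args$s_max, step = args$step)
    roles <- module_roles(nw$network)
    ens <- maslov_sneppen_ensemble(nw$network, n_random = args$n_random,
                                   n_swaps_per_edge = args$n_swaps_per_edge,
                                   seed = stage_seed(config$seed, "network"))
    res$network <- nw; res$roles <- roles; res$ensemble <- ens
    write_edge_list(nw$network, file.path(config$out, "edges.tsv"))
    written <- c(written, file.path(config$out, "edges.tsv"))
    emit(roles, "roles.tsv", "network", args, id_name = "row")
    emit(ens$summary, "network_null_ensemble.tsv", "network", args,
         id_name = "row")
  }

  if ("screen" %in% config$stages) {
    need(table, "screen", "abundance table")
    need(res$cohesion, "screen", "cohesion stage output")
    args <- utils::modifyList(list(n_trees = 500, n_perm = 1000,
                                   cv_repeats = 5, cv_folds = 10,
                                   alpha = 0.05), config$screen)
    ks <- screen_keystones(table, res$cohesion$pos_cohesion,
                           n_trees = args$n_trees, n_perm = args$n_perm,
                           cv_repeats = args$cv_repeats,
                           cv_folds = args$cv_folds, alpha = args$alpha,
                           seed = stage_seed(config$seed, "screen"))
    res$screen <- ks
    emit(ks$report, "keystone_report.tsv", "screen", args, id_name = "row")
  }

  if ("mcn" %in% config$stages) {
    need(table, "mcn", "abundance table")
    need(metadata, "mcn", "sample metadata")
    traits <- config$mcn$traits
    if (is.null(traits) && !is.null(res$simulate))
      traits <- data.frame(taxon_id = rownames(res$simulate$traits),
                           rrn_copy_number = res$simulate$traits$copy_number,
                           match_level = "species", stringsAsFactors = FALSE)
    need(traits, "mcn", "rrn trait table")
    mr <- mcn(table, traits)
    model <- mcn_model(mr, metadata)
    res$mcn <- mr; res$mcn_model <- model
    emit(mr$samples, "mcn.tsv", "mcn", list(), id_name = "row")
    emit(model, "mcn_model.tsv", "mcn", list(), id_name = "row")
  }

  if ("modules" %in% config$stages) {
    need(res$genomes, "modules", "genome annotations (simulate stage)")
    args <- utils::modifyList(list(k = 7, completeness_cutoff = 0.67,
                                   member_fraction = 0.5), config$modules)
    cm <- completeness_matrix(res$genomes$annotations,
                              res$genomes$module_defs)
    grp <- group_genomes(cm, k = args$k)
    gm <- group_complete_modules(cm, grp, args$completeness_cutoff,
                                 args$member_fraction)
    sets <- shared_unique_sets(gm)
    res$completeness <- cm; res$groups <- grp; res$group_modules <- gm
    res$module_sets <- sets
    emit(cm, "completeness_matrix.tsv", "modules", args, id_name = "genome_id")
    emit(data.frame(group = grp, row.names = names(grp)), "genome_groups.tsv",
         "modules", args, id_name = "genome_id")
    emit(sets, "module_intersections.tsv", "modules", args, id_name = "row")
  }

  if ("interactions" %in% config$stages) {
    need(res$coculture, "interactions", "co-culture records (simulate stage)")
    args <- utils::modifyList(list(scale = "relative", alpha = 0.05,
                                   mode = "gated"), config$interactions)
    calls <- call_interactions(res$coculture$records, scale = args$scale,
                               alpha = args$alpha, mode = args$mode)
    summ <- summarize_interactions(calls, by = "temperature")
    res$interactions <- calls; res$interaction_summary <- summ
    emit(as.data.frame(calls), "interaction_calls.tsv", "interactions", args,
         id_name = "row")
    emit(summ$groups, "interaction_summary.tsv", "interactions", args,
         id_name = "row")
  }

  manifest <- list(package = "compostcoop",
                   version = as.character(utils::packageVersion("compostcoop")),
                   seed = config$seed,
                   stage_seeds = lapply(stats::setNames(nm = c(
                     "simulate", "coculture", "genomes", "cohesion", "network",
                     "screen", "mcn", "modules", "interactions")),
                     function(s) stage_seed(config$seed, s)),
                   stages = config$stages,
                   parameters = config[setdiff(names(config), c("out"))],
                   files = as.list(tools::md5sum(written)))
  jsonlite::write_json(manifest, file.path(config$out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(res)
}

# md5 of a canonicalized parameter list (provenance headers)
digest_params <- function(params) {
  s <- paste(names(unlist(params)), format(unlist(params), digits = 15),
             sep = "=", collapse = ";")
  f <- tempfile(); on.exit(unlink(f))
  writeLines(s, f)
  unname(tools::md5sum(f))
}
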
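default_pipeline_config <- function() {
  list(
    seed = 1L,
    growth = list(n_wells = 8, noise_sd = 0.005, window = 10),
    competition = list(n_lines = 12, bottleneck_size = 4.706e4, dilution = 1000,
                       mutation_rate_beneficial = 1e-7, s = 0.08,
                       n_transfers = 45, by_generation = 450,
                       fixation_threshold = 0.95),
    phenotype = list(n_clones_per_group = c(9, 11),
                     sigma_interaction = c(0.06, 0.02), n_conditions = 11),
    bsa = list(n_tetrads = 40, pool_size = 9, coverage = 200, reps = 10000,
               pool_sizes = c(5, 9, 10, 18, 21),
               thr_good = 0.70, thr_diff = 0.45),
    variants = list(n_clones = 9, min_depth = 20, min_freq_percent = 35,
                    cnv_delta = 0.8),
    enrichment = list(alpha = 0.05)
  )
}

validate_config <- function(config) {
  defaults <- default_pipeline_config()
  if (is.null(config)) config <- list()
  if (is.character(config) && length(config) == 1L) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading a YAML config requires the 'yaml' package", call. = FALSE)
    }
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML file path", call. = FALSE)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0L) {
    stop("unknown config section(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  for (sec in names(config)) {
    if (sec == "seed") next
    bad <- setdiff(names(config[[sec]]), names(defaults[[sec]]))
    if (length(bad) > 0L) {
      stop("unknown key(s) in config section '", sec, "': ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    defaults[[sec]][names(config[[sec]])] <- config[[sec]]
  }
  if (!is.null(config$seed)) defaults$seed <- config$seed
  defaults
}

#' Run the full synthetic-data demonstration pipeline
#'
#' Generates every input with the synthetic-data module and runs each
#' analysis stage over it in dependency order: growth curves -> maximal
#' rates; competition trajectories -> fixation summary; fitness matrices ->
#' normalization, clustering, PCA, distance matrices and the two divergence
#' tests; tetrads -> pools -> pool sequencing -> null thresholds ->
#' strong-effect classification; variant tables -> filtering, evolved-
#' mutation calls and enrichment. All stage outputs are written as TSV/JSON
#' under `out_dir` together with a run manifest recording the package
#' version, seed, applied thresholds and output file digests.
#'
#' @param config A configuration list (see `default_pipeline_config` in the
#'   sources for the schema), a YAML file path, or `NULL` for the defaults.
#' @param out_dir Fresh output directory (created; inputs are never
#'   modified).
#' @param seed Root seed; overrides the config seed. Per-stage seeds are
#'   derived deterministically from it.
#' @return The run manifest, invisibly; stage results as the `results`
#'   attribute.
#' @export
run_pipeline <- function(config = NULL, out_dir = tempfile("hubevolve_run_"),
                         seed = NULL) {
  cfg <- validate_config(config)
  if (!is.null(seed)) cfg$seed <- seed
  root_seed <- as.integer(cfg$seed)
  stage_seed <- function(i) (root_seed * 101L + i * 7919L) %% .Machine$integer.max
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  results <- list()

  # --- growth fitness ---
  gw <- gen_growth_curves(n_wells = cfg$growth$n_wells,
                          noise_sd = cfg$growth$noise_sd,
                          seed = stage_seed(1L))
  rates <- do.call(rbind, lapply(gw$curves, function(cv) {
    fv <- max_growth_rate(cv, window = cfg$growth$window)
    data.frame(strain = fv$strain_id, condition = fv$condition,
               replicate = fv$replicate, rate = fv$rate,
               window_start = fv$window_start)
  }))
  write_tsv(rates, file.path(out_dir, "growth_rates.tsv"))
  results$growth <- list(rates = rates, truth = gw$truth)

  # --- competition ---
  cmp <- gen_competition(n_lines = cfg$competition$n_lines,
                         bottleneck_size = cfg$competition$bottleneck_size,
                         dilution = cfg$competition$dilution,
                         mutation_rate_beneficial = cfg$competition$mutation_rate_beneficial,
                         s = cfg$competition$s,
                         n_transfers = cfg$competition$n_transfers,
                         seed = stage_seed(2L))
  fix <- fixation_summary(cmp$trajectories,
                          by_generation = cfg$competition$by_generation,
                          threshold = cfg$competition$fixation_threshold)
  write_tsv(fix$calls, file.path(out_dir, "fixation_calls.tsv"))
  results$competition <- list(summary = fix, truth = cmp$truth)

  # --- phenotype divergence ---
  fm <- gen_fitness_matrix(n_clones_per_group = cfg$phenotype$n_clones_per_group,
                           sigma_interaction = cfg$phenotype$sigma_interaction,
                           n_conditions = cfg$phenotype$n_conditions,
                           seed = stage_seed(3L))
  split_fit <- split(fm$fitness, fm$fitness$group)
  mats <- lapply(split_fit, fitness_matrix)
  norm1 <- normalize_by_condition_mean(mats[[1]])
  dend <- hierarchical_cluster(norm1, axis = "strains")
  pca <- pca_explained_variance(mats[[1]])
  d1 <- condition_distance_matrix(mats[[1]])
  d2 <- condition_distance_matrix(mats[[2]])
  div <- divergence_test(d1, d2)
  varres <- improvement_variance_test(mats[[1]], mats[[2]])
  write_tsv(as.data.frame(as.matrix(d1)), file.path(out_dir, "condition_distances_group1.tsv"))
  write_tsv(as.data.frame(as.matrix(d2)), file.path(out_dir, "condition_distances_group2.tsv"))
  jsonlite::write_json(
    list(divergence = list(W = div$W, p = div$p),
         variance = list(t = varres$t, df = varres$df, p = varres$p),
         pca_explained = pca$explained_fraction),
    file.path(out_dir, "divergence_tests.json"), auto_unbox = TRUE, digits = NA)
  results$phenotype <- list(divergence = div, variance = varres, pca = pca,
                            dendrogram = dend, truth = fm$truth)

  # --- BSA mapping ---
  td <- gen_tetrads(n_tetrads = cfg$bsa$n_tetrads, seed = stage_seed(4L))
  pools <- assign_pools(td$spores, td$evolved_ref, td$ancestral_ref,
                        max_pool_size = cfg$bsa$pool_size)
  ps <- gen_poolseq(pools, td$genotypes, coverage = cfg$bsa$coverage,
                    seed = stage_seed(5L))
  thr <- null_thresholds(cfg$bsa$pool_sizes, coverage = cfg$bsa$coverage,
                         reps = cfg$bsa$reps, seed = stage_seed(6L))
  cls <- classify_strong_effect(ps, thr_good = cfg$bsa$thr_good,
                                thr_diff = cfg$bsa$thr_diff)
  write_tsv(thr, file.path(out_dir, "null_thresholds.tsv"))
  write_tsv(cls, file.path(out_dir, "strong_effect_calls.tsv"))
  results$bsa <- list(classification = cls, thresholds = thr, truth = td$truth)

  # --- variants + enrichment ---
  va <- gen_variants_and_annotation(n_clones = cfg$variants$n_clones,
                                    seed = stage_seed(7L))
  filtered <- lapply(va$clones, filter_variants,
                     min_depth = cfg$variants$min_depth,
                     min_freq_percent = cfg$variants$min_freq_percent)
  calls <- call_evolved_mutations(filtered, va$ancestor)
  # overlap-collapsed records carry semicolon-joined gene labels; enrichment
  # is gene-level, so split them back out
  query <- unique(unlist(strsplit(as.character(calls$mutations$gene), ";")))
  enr <- run_enrichment(query, va$annotation,
                        alpha = cfg$enrichment$alpha)
  write_tsv(calls$mutations, file.path(out_dir, "evolved_mutations.tsv"))
  write_tsv(enr, file.path(out_dir, "enrichment.tsv"))
  results$variants <- list(calls = calls, enrichment = enr, truth = va$truth)

  outputs <- list.files(out_dir, full.names = TRUE)
  manifest <- list(
    package = "hubevolve",
    version = as.character(utils::packageVersion("hubevolve")),
    seed = root_seed,
    parameters = cfg,
    thresholds_applied = list(
      window = cfg$growth$window,
      fixation_threshold = cfg$competition$fixation_threshold,
      min_depth = cfg$variants$min_depth,
      min_freq_percent = cfg$variants$min_freq_percent,
      cnv_delta = cfg$variants$cnv_delta,
      thr_good = cfg$bsa$thr_good,
      thr_diff = cfg$bsa$thr_diff,
      alpha = cfg$enrichment$alpha
    ),
    output_digests = as.list(tools::md5sum(outputs))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  attr(manifest, "results") <- results
  invisible(manifest)
}
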
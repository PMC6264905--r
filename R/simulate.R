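#' Generate noisy logistic growth curves
#'
#' Simulates plate-reader wells growing logistically,
#' od(t) = K od0 e^(rt) / (K + od0 (e^(rt) - 1)), starting at od0 = 0.1
#' (the standard inoculation density) with additive Gaussian reading noise.
#' The analytic maximal slope of such a curve is r K / 4, attained at the
#' inflection point.
#'
#' @param n_wells Number of wells.
#' @param rate_range Range from which each well's true rate r (per hour) is
#'   drawn uniformly.
#' @param capacity Carrying capacity K in OD595 units.
#' @param noise_sd Standard deviation of additive OD noise (>= 0).
#' @param interval_min Sampling interval in minutes (default 10).
#' @param duration_min Total measured time in minutes.
#' @param od0 Inoculation density (default 0.1 OD595).
#' @param seed Optional integer seed.
#' @return List with `curves` (list of [growth_curve()] objects) and `truth`
#'   (data frame of per-well r, K and the analytic peak slope rK/4).
#' @export
gen_growth_curves <- function(n_wells = 8, rate_range = c(0.05, 0.4),
                              capacity = 1.0, noise_sd = 0.005,
                              interval_min = 10, duration_min = 1440,
                              od0 = 0.1, seed = NULL) {
  if (noise_sd < 0) stop("'noise_sd' must be non-negative", call. = FALSE)
  stop_if_not_scalar_number(capacity, "capacity", positive = TRUE)
  stop_if_not_scalar_number(od0, "od0", positive = TRUE)
  with_seed(seed, {
    times <- seq(0, duration_min, by = interval_min)
    r <- stats::runif(n_wells, rate_range[1], rate_range[2])
    curves <- vector("list", n_wells)
    for (w in seq_len(n_wells)) {
      th <- times / 60
      od <- capacity * od0 * exp(r[w] * th) /
        (capacity + od0 * (exp(r[w] * th) - 1))
      od <- od + stats::rnorm(length(od), 0, noise_sd)
      od[od < 0] <- 0
      curves[[w]] <- growth_curve(times, od, strain_id = sprintf("well%02d", w),
                                  condition = "synthetic", replicate = 1L)
    }
    truth <- data.frame(well = sprintf("well%02d", seq_len(n_wells)),
                        r = r, K = capacity, peak_slope = r * capacity / 4)
    list(curves = curves, truth = truth)
  })
}

#' Simulate two-color serial-transfer competition dynamics
#'
#' Wright-Fisher-style serial-transfer model of the fluorescent two-color
#' competition design: two neutral color labels start near 1:1; each daily
#' transfer grows the culture deterministically from the bottleneck N0 to
#' N0 x dilution (log2(dilution) generations) with fitness weights 1 and
#' (1 + s) per generation for wild-type and beneficial-mutant classes,
#' seeds new beneficial mutants on each color background at
#' `mutation_rate_beneficial` per cell division, and then bottlenecks back
#' to N0 by multinomial sampling.
#'
#' @param n_lines Number of independently evolving lines.
#' @param bottleneck_size Cells transferred each day (N0 >= 10).
#' @param dilution Fold dilution per transfer (default 1000, about 10
#'   generations per day).
#' @param mutation_rate_beneficial Beneficial mutation rate per cell
#'   division (>= 0).
#' @param s Selection coefficient of beneficial mutants (>= 0).
#' @param n_transfers Number of daily transfers.
#' @param sample_every Record the green frequency every this many transfers
#'   (plus the initial point).
#' @param initial_green Initial green frequency (default 0.5).
#' @param seed Optional integer seed.
#' @return List with `trajectories` (list of [competition_trajectory()])
#'   and `truth` (per line: transfer of first surviving mutant lineage and
#'   the fixation generation at the 95% threshold, `NA` if never reached).
#' @export
gen_competition <- function(n_lines = 12, bottleneck_size = 4.706e4,
                            dilution = 1000, mutation_rate_beneficial = 1e-7,
                            s = 0.08, n_transfers = 45, sample_every = 5,
                            initial_green = 0.5, seed = NULL) {
  if (bottleneck_size < 10) stop("'bottleneck_size' must be >= 10", call. = FALSE)
  if (s < 0) stop("'s' must be non-negative", call. = FALSE)
  if (mutation_rate_beneficial < 0) stop("mutation rate must be non-negative", call. = FALSE)
  g <- generations_per_transfer(dilution)
  N0 <- round(bottleneck_size)
  Nfinal <- N0 * dilution
  with_seed(seed, {
    sample_at <- unique(c(0L, seq(sample_every, n_transfers, by = sample_every),
                          n_transfers))
    gens <- sample_at * g

    if (mutation_rate_beneficial == 0) {
      # no mutants can arise: colors drift neutrally; vectorize across lines
      green <- stats::rbinom(n_lines, N0, initial_green)
      freqs <- matrix(NA_real_, nrow = n_lines, ncol = length(sample_at))
      freqs[, 1] <- green / N0
      col <- 2L
      for (tr in seq_len(n_transfers)) {
        green <- stats::rbinom(n_lines, N0, green / N0)
        if (tr %in% sample_at) {
          freqs[, col] <- green / N0
          col <- col + 1L
        }
      }
      trajectories <- lapply(seq_len(n_lines), function(l) {
        competition_trajectory(gens, freqs[l, ], line_id = sprintf("line%02d", l))
      })
      truth <- data.frame(line_id = sprintf("line%02d", seq_len(n_lines)),
                          first_mutant_transfer = NA_real_,
                          fixation_generation = vapply(trajectories, function(tr) {
                            fx <- detect_fixation(tr)
                            if (is.null(fx)) NA_real_ else fx$generation
                          }, numeric(1)))
      return(list(trajectories = trajectories, truth = truth))
    }

    # within-transfer growth: deterministic doubling in n_steps increments so
    # that mutations arising early in a growth cycle expand before the
    # bottleneck, as they do in the culture
    n_steps <- max(1L, ceiling(g))
    f_step <- dilution^(1 / n_steps)          # wild-type per-step growth factor
    w_step <- (1 + s)^(g / n_steps)           # extra mutant advantage per step
    trajectories <- vector("list", n_lines)
    first_mut <- rep(NA_real_, n_lines)
    for (l in seq_len(n_lines)) {
      # classes: green wt, green mut, red wt, red mut
      counts <- c(stats::rbinom(1, N0, initial_green), 0, 0, 0)
      counts[3] <- N0 - counts[1]
      freqs <- numeric(length(sample_at))
      freqs[1] <- (counts[1] + counts[2]) / N0
      col <- 2L
      for (tr in seq_len(n_transfers)) {
        grown <- counts
        for (j in seq_len(n_steps)) {
          before <- grown
          grown <- grown * f_step * c(1, w_step, 1, w_step)
          for (color in c(1, 3)) {
            new_cells <- grown[color] - before[color]
            m <- stats::rpois(1, mutation_rate_beneficial * max(new_cells, 0))
            m <- min(m, grown[color])
            grown[color] <- grown[color] - m
            grown[color + 1] <- grown[color + 1] + m
          }
        }
        grown <- grown / sum(grown) * Nfinal
        if (is.na(first_mut[l]) && (grown[2] + grown[4]) > 0) first_mut[l] <- tr
        counts <- as.vector(stats::rmultinom(1, N0, grown / sum(grown)))
        if (tr %in% sample_at) {
          freqs[col] <- (counts[1] + counts[2]) / N0
          col <- col + 1L
        }
      }
      trajectories[[l]] <- competition_trajectory(gens, freqs,
                                                  line_id = sprintf("line%02d", l))
    }
    truth <- data.frame(
      line_id = sprintf("line%02d", seq_len(n_lines)),
      first_mutant_transfer = first_mut,
      fixation_generation = vapply(trajectories, function(tr) {
        fx <- detect_fixation(tr)
        if (is.null(fx)) NA_real_ else fx$generation
      }, numeric(1))
    )
    list(trajectories = trajectories, truth = truth)
  })
}

#' Simulate tetrads segregating planted causal loci
#'
#' Each tetrad carries four haploid spores; every heterozygous locus
#' segregates exactly 2:2 within a tetrad and loci assort independently
#' (no recombination map). Spore fitness is
#' baseline x (1 + sum of carried causal effects) + Gaussian noise, so the
#' planted effects act as selection coefficients relative to the ancestral
#' baseline.
#'
#' @param n_tetrads Number of four-viable-spore tetrads.
#' @param causal_effects Numeric vector of relative fitness effects of the
#'   planted causal loci (the evolved parent carries all of them).
#' @param n_neutral_loci Number of additional neutral (unlinked) loci.
#' @param baseline Ancestral fitness (OD595/hour scale).
#' @param fitness_noise_sd Absolute measurement noise on spore fitness.
#' @param seed Optional integer seed.
#' @return List with `spores` (data frame: `tetrad`, `spore`, `fitness`),
#'   `genotypes` (spore x locus 0/1 matrix, 1 = evolved allele) and `truth`
#'   (locus table with effects; causal loci first, named `causal_*`).
#' @export
gen_tetrads <- function(n_tetrads = 40, causal_effects = c(0.12, 0.15, 0.18),
                        n_neutral_loci = 20, baseline = 0.30,
                        fitness_noise_sd = 0.01, seed = NULL) {
  if (n_tetrads < 1) stop("'n_tetrads' must be >= 1", call. = FALSE)
  if (fitness_noise_sd < 0) stop("'fitness_noise_sd' must be >= 0", call. = FALSE)
  n_causal <- length(causal_effects)
  n_loci <- n_causal + n_neutral_loci
  loci <- c(if (n_causal > 0) sprintf("causal_%02d", seq_len(n_causal)),
            if (n_neutral_loci > 0) sprintf("neutral_%02d", seq_len(n_neutral_loci)))
  with_seed(seed, {
    n_spores <- 4L * n_tetrads
    geno <- matrix(0L, nrow = n_spores, ncol = n_loci,
                   dimnames = list(NULL, loci))
    spore_id <- character(n_spores)
    tetrad_id <- character(n_spores)
    for (t in seq_len(n_tetrads)) {
      rows <- (4L * (t - 1L) + 1L):(4L * t)
      tetrad_id[rows] <- sprintf("T%03d", t)
      spore_id[rows] <- sprintf("T%03d.%d", t, 1:4)
      for (j in seq_len(n_loci)) {
        geno[rows[sample.int(4L, 2L)], j] <- 1L  # 2:2 segregation per locus
      }
    }
    effect_vec <- c(causal_effects, rep(0, n_neutral_loci))
    fitness <- baseline * (1 + as.vector(geno[, seq_len(n_loci), drop = FALSE] %*% effect_vec)) +
      stats::rnorm(n_spores, 0, fitness_noise_sd)
    spores <- data.frame(tetrad = tetrad_id, spore = spore_id, fitness = fitness)
    rownames(geno) <- spore_id
    truth <- data.frame(locus = loci, effect = effect_vec,
                        causal = effect_vec != 0)
    list(spores = spores, genotypes = geno, truth = truth,
         evolved_ref = baseline * (1 + sum(causal_effects)),
         ancestral_ref = baseline)
  })
}

#' Simulate pooled sequencing of assigned spore pools
#'
#' For each locus, alternate-allele reads in a pool are drawn as
#' Binomial(coverage, carriers / pool size), modelling equimolar DNA
#' contribution per spore.
#'
#' @param pools A pool assignment from [assign_pools()] (uses `good_pool`
#'   and `bad_pool` spore ids).
#' @param genotypes Spore x locus 0/1 matrix with spore ids as row names.
#' @param coverage Read depth per locus (default 200).
#' @param seed Optional integer seed.
#' @return Data frame with per-locus `good_alt`, `good_depth`, `bad_alt`,
#'   `bad_depth`, `good_freq`, `bad_freq`.
#' @export
gen_poolseq <- function(pools, genotypes, coverage = 200, seed = NULL) {
  good <- pools$good_pool
  bad <- pools$bad_pool
  if (length(good) == 0L || length(bad) == 0L) {
    stop("both pools must be non-empty", call. = FALSE)
  }
  missing <- setdiff(c(good, bad), rownames(genotypes))
  if (length(missing) > 0L) {
    stop("pooled spore(s) missing from genotypes: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  with_seed(seed, {
    p_good <- colMeans(genotypes[good, , drop = FALSE])
    p_bad <- colMeans(genotypes[bad, , drop = FALSE])
    good_alt <- stats::rbinom(length(p_good), coverage, p_good)
    bad_alt <- stats::rbinom(length(p_bad), coverage, p_bad)
    data.frame(
      locus = colnames(genotypes),
      good_alt = good_alt, good_depth = coverage,
      bad_alt = bad_alt, bad_depth = coverage,
      good_freq = good_alt / coverage,
      bad_freq = bad_alt / coverage
    )
  })
}

#' Simulate a strain x condition fitness matrix with group-specific
#' interaction variance
#'
#' Each value is condition baseline + clone main effect + clone-by-condition
#' interaction + replicate noise, with the interaction standard deviation
#' set per group. A larger interaction variance produces clones whose
#' fitness ranks differ more between conditions — the phenotypic-divergence
#' signal the correlation-distance and variance tests are designed to pick
#' up.
#'
#' @param n_clones_per_group Integer vector of clones per group, e.g.
#'   `c(9, 11)` for the evolved replacement and control groups.
#' @param n_conditions Number of assay conditions (default 11).
#' @param sigma_interaction Per-group interaction standard deviations
#'   (same length as `n_clones_per_group`).
#' @param sigma_replicate Replicate noise standard deviation.
#' @param n_replicates Replicates per clone x condition (default 3).
#' @param baseline_mean,baseline_sd Distribution of condition baselines
#'   (OD595/hour scale).
#' @param sigma_clone Standard deviation of clone main effects.
#' @param seed Optional integer seed.
#' @return List with `fitness` (long data frame: `group`, `strain`,
#'   `condition`, `replicate`, `rate`) and `truth` (the sigma values).
#' @export
gen_fitness_matrix <- function(n_clones_per_group = c(9, 11), n_conditions = 11,
                               sigma_interaction = c(0.06, 0.02),
                               sigma_replicate = 0.01, n_replicates = 3,
                               baseline_mean = 0.35, baseline_sd = 0.05,
                               sigma_clone = 0.02, seed = NULL) {
  if (length(sigma_interaction) != length(n_clones_per_group)) {
    stop("'sigma_interaction' needs one value per group", call. = FALSE)
  }
  if (any(c(sigma_interaction, sigma_replicate) < 0)) {
    stop("standard deviations must be non-negative", call. = FALSE)
  }
  with_seed(seed, {
    conditions <- sprintf("cond%02d", seq_len(n_conditions))
    baselines <- stats::rnorm(n_conditions, baseline_mean, baseline_sd)
    rows <- list()
    for (grp in seq_along(n_clones_per_group)) {
      for (cl in seq_len(n_clones_per_group[grp])) {
        main <- stats::rnorm(1, 0, sigma_clone)
        inter <- stats::rnorm(n_conditions, 0, sigma_interaction[grp])
        for (cond in seq_len(n_conditions)) {
          rows[[length(rows) + 1L]] <- data.frame(
            group = sprintf("group%d", grp),
            strain = sprintf("g%d_clone%02d", grp, cl),
            condition = conditions[cond],
            replicate = seq_len(n_replicates),
            rate = baselines[cond] + main + inter[cond] +
              stats::rnorm(n_replicates, 0, sigma_replicate)
          )
        }
      }
    }
    fitness <- do.call(rbind, rows)
    truth <- data.frame(group = sprintf("group%d", seq_along(n_clones_per_group)),
                        sigma_interaction = sigma_interaction,
                        sigma_replicate = sigma_replicate,
                        sigma_clone = sigma_clone)
    list(fitness = fitness, truth = truth)
  })
}

#' Simulate evolved/ancestral variant tables and a category annotation
#'
#' Builds a cohort of evolved clones with: private evolved mutations; a set
#' of variants shared by several clones but absent from the ancestor
#' (pre-existing standing variation that the caller should flag); sites
#' double-called because they overlap two open reading frames; boundary
#' records sitting exactly on the depth/frequency filter thresholds (which
#' strict filters must drop); and ancestor-shared background SNPs. A gene
#' annotation with one planted over-represented category among the mutated
#' genes is generated alongside.
#'
#' @param n_clones Number of evolved clones.
#' @param n_private Private evolved mutations per clone.
#' @param n_shared_ancestral Variants shared by >= 2 clones, absent from the
#'   ancestor (planted pre-existing SNPs).
#' @param n_overlap_pairs Sites per clone double-called in two overlapping
#'   genes.
#' @param n_boundary Boundary records per clone at depth exactly
#'   `min_depth` or frequency exactly `min_freq` (to be dropped by strict
#'   filters).
#' @param n_background Ancestor SNPs also present in every clone.
#' @param n_genome_genes Genome background size for the annotation.
#' @param n_categories Number of annotation categories.
#' @param planted_fold Over-representation factor of the planted enriched
#'   category among mutated genes (default 10).
#' @param planted_category_size Genome-side size of the planted category
#'   (default 30 genes).
#' @param min_depth,min_freq The filter thresholds the boundary records sit
#'   on (defaults 20 and 35).
#' @param seed Optional integer seed.
#' @return List with `ancestor`, `clones` (named list of variant data
#'   frames), `annotation` (an [annotation_set()]), and `truth` (planted
#'   shared keys, boundary keys, planted enriched category and the mutated
#'   gene set).
#' @export
gen_variants_and_annotation <- function(n_clones = 9, n_private = 20,
                                        n_shared_ancestral = 4,
                                        n_overlap_pairs = 2, n_boundary = 2,
                                        n_background = 30,
                                        n_genome_genes = 800, n_categories = 40,
                                        planted_fold = 10,
                                        planted_category_size = 30,
                                        min_depth = 20, min_freq = 35,
                                        seed = NULL) {
  with_seed(seed, {
    genome_genes <- sprintf("GENE%04d", seq_len(n_genome_genes))
    # annotation: categories of varying size; first category is the planted one
    cat_names <- sprintf("CAT%02d", seq_len(n_categories))
    cat_sizes <- c(planted_category_size,
                   pmax(2L, stats::rpois(n_categories - 1L, 12)))
    memberships <- do.call(rbind, lapply(seq_len(n_categories), function(i) {
      data.frame(gene = sample(genome_genes, cat_sizes[i]),
                 category = cat_names[i])
    }))
    annotation <- annotation_set(memberships, genome_genes)
    planted <- cat_names[1]
    planted_genes <- annotation$categories[[planted]]

    # choose mutated genes so the planted category is ~planted_fold
    # over-represented in the query relative to its genome proportion
    n_mut_genes <- n_clones * n_private  # upper bound; genes may repeat
    base_prop <- length(planted_genes) / n_genome_genes
    target_prop <- min(0.9, planted_fold * base_prop)
    pick_gene <- function(n) {
      from_planted <- stats::rbinom(1, n, target_prop)
      c(sample(planted_genes, from_planted, replace = TRUE),
        sample(setdiff(genome_genes, planted_genes), n - from_planted,
               replace = TRUE))
    }

    chrom <- function(n) sample(sprintf("chr%02d", 1:16), n, replace = TRUE)
    bases <- c("A", "C", "G", "T")
    new_site <- function(n, gene) {
      data.frame(
        chromosome = chrom(n),
        position = sample.int(1e6, n),
        ref = sample(bases, n, replace = TRUE),
        alt = sample(bases, n, replace = TRUE),
        gene = gene,
        effect = sample(c("nonsynonymous", "synonymous", "indel", "intergenic"),
                        n, replace = TRUE, prob = c(0.5, 0.25, 0.1, 0.15)),
        depth = min_depth + 1 + stats::rpois(n, 80),
        allele_freq = stats::runif(n, 60, 100)
      )
    }

    ancestor <- new_site(n_background, sample(genome_genes, n_background, replace = TRUE))
    shared <- new_site(n_shared_ancestral,
                       sample(genome_genes, n_shared_ancestral, replace = TRUE))
    shared_carriers <- lapply(seq_len(n_shared_ancestral), function(i) {
      sort(sample.int(n_clones, sample(2:n_clones, 1)))
    })

    clones <- list()
    mutated_genes <- character(0)
    boundary_keys <- character(0)
    for (cl in seq_len(n_clones)) {
      priv <- new_site(n_private, pick_gene(n_private))
      mutated_genes <- c(mutated_genes, priv$gene)
      # overlapping-ORF double calls: duplicate a private site under a second gene
      if (n_overlap_pairs > 0) {
        dup <- priv[seq_len(min(n_overlap_pairs, nrow(priv))), , drop = FALSE]
        dup$gene <- sample(genome_genes, nrow(dup), replace = TRUE)
        priv <- rbind(priv, dup)
      }
      # boundary records exactly on the strict thresholds
      if (n_boundary > 0) {
        bnd <- new_site(n_boundary, sample(genome_genes, n_boundary, replace = TRUE))
        half <- seq_len(n_boundary) %% 2 == 0
        bnd$depth[!half] <- min_depth
        bnd$allele_freq[half] <- min_freq
        boundary_keys <- c(boundary_keys, variant_key(bnd))
        priv <- rbind(priv, bnd)
      }
      tab <- rbind(priv, ancestor,
                   shared[vapply(shared_carriers, function(cc) cl %in% cc, logical(1)), ,
                          drop = FALSE])
      clones[[sprintf("E%d", cl)]] <- tab
    }
    truth <- list(
      shared_keys = variant_key(shared),
      boundary_keys = boundary_keys,
      planted_category = planted,
      mutated_genes = unique(mutated_genes)
    )
    list(ancestor = ancestor, clones = clones, annotation = annotation,
         truth = truth)
  })
}
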
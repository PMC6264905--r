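test_that("generators are reproducible given the same seed", {
  g1 <- gen_growth_curves(n_wells = 3, seed = 5)
  g2 <- gen_growth_curves(n_wells = 3, seed = 5)
  expect_equal(g1, g2)
  c1 <- gen_competition(n_lines = 3, n_transfers = 10, seed = 5)
  c2 <- gen_competition(n_lines = 3, n_transfers = 10, seed = 5)
  expect_equal(c1, c2)
  t1 <- gen_tetrads(n_tetrads = 5, seed = 5)
  expect_equal(t1, gen_tetrads(n_tetrads = 5, seed = 5))
  v1 <- gen_variants_and_annotation(n_clones = 3, seed = 5)
  expect_equal(v1, gen_variants_and_annotation(n_clones = 3, seed = 5))
  # and truth records ship alongside every dataset
  expect_named(g1, c("curves", "truth"))
  expect_true(all(c("spores", "genotypes", "truth") %in% names(t1)))
})

test_that("noiseless growth curves start at the inoculation density and hit rK/4", {
  g <- gen_growth_curves(n_wells = 4, rate_range = c(0.2, 0.3), noise_sd = 0,
                         duration_min = 2880, seed = 3)
  for (i in seq_along(g$curves)) {
    cv <- g$curves[[i]]
    expect_equal(cv$od[1], 0.1, tolerance = 1e-9)
    est <- max_growth_rate(cv)$rate
    expect_equal(est, g$truth$peak_slope[i], tolerance = 0.02)
  }
  expect_error(gen_growth_curves(noise_sd = -1), "non-negative")
})

test_that("every locus segregates exactly 2:2 within each tetrad", {
  td <- gen_tetrads(n_tetrads = 12, seed = 8)
  tet <- rep(seq_len(12), each = 4)
  for (j in seq_len(ncol(td$genotypes))) {
    counts <- tapply(td$genotypes[, j], tet, sum)
    expect_true(all(counts == 2))
  }
})

test_that("with no causal effects the pools show ~50% allele frequencies", {
  freqs <- vapply(1:30, function(i) {
    td <- gen_tetrads(n_tetrads = 30, causal_effects = numeric(0),
                      n_neutral_loci = 8, seed = 200 + i)
    # no fitness signal: pool on arbitrary references around the baseline
    pa <- assign_pools(td$spores, evolved_ref = 0.31, ancestral_ref = 0.29,
                       tolerance = 0.05)
    if (length(pa$good_pool) < 3) return(NA_real_)
    mean(colMeans(td$genotypes[pa$good_pool, , drop = FALSE]))
  }, numeric(1))
  expect_equal(mean(freqs, na.rm = TRUE), 0.5, tolerance = 0.05)
})

test_that("pool sequencing draws binomial reads from carrier fractions", {
  td <- gen_tetrads(n_tetrads = 10, seed = 4)
  pa <- assign_pools(td$spores, td$evolved_ref, td$ancestral_ref)
  ps <- gen_poolseq(pa, td$genotypes, coverage = 200, seed = 4)
  expect_true(all(ps$good_alt <= ps$good_depth))
  expect_equal(ps$good_freq, ps$good_alt / 200)

  # deterministic limits: all carriers / no carriers
  geno <- matrix(c(1, 1, 0, 0), nrow = 2, ncol = 2,
                 dimnames = list(c("s1", "s2"), c("all", "none")))
  pools <- list(good_pool = c("s1", "s2"), bad_pool = c("s1", "s2"))
  ps2 <- gen_poolseq(pools, geno, coverage = 100, seed = 1)
  expect_equal(ps2$good_alt[ps2$locus == "all"], 100)
  expect_equal(ps2$good_alt[ps2$locus == "none"], 0)

  # mean observed frequency tracks the carrier fraction within 3 SE
  geno3 <- matrix(c(1, 0, 0, 1, 1, 0, 0, 0), nrow = 4,
                  dimnames = list(sprintf("s%d", 1:4), c("half", "quarter")))
  pools3 <- list(good_pool = rownames(geno3), bad_pool = rownames(geno3))
  reps <- vapply(1:300, function(i) {
    gen_poolseq(pools3, geno3, coverage = 200, seed = 5000 + i)$good_freq
  }, numeric(2))
  for (j in 1:2) {
    p <- mean(geno3[, j])
    se <- stats::sd(reps[j, ]) / sqrt(ncol(reps))
    expect_lt(abs(mean(reps[j, ]) - p), 3 * se)
  }
  expect_error(gen_poolseq(list(good_pool = character(0), bad_pool = "s1"),
                           geno, 100), "non-empty")
})

test_that("competition simulator uses ~10 generations per 1000-fold transfer and responds to s", {
  cmp <- gen_competition(n_lines = 2, n_transfers = 4, sample_every = 1, seed = 2)
  gens <- cmp$trajectories[[1]]$generations
  expect_equal(diff(gens)[1], generations_per_transfer(1000), tolerance = 1e-9)

  # stronger selection fixes sooner (median over replicate lines)
  strong <- gen_competition(n_lines = 40, s = 0.12, mutation_rate_beneficial = 2e-7,
                            n_transfers = 60, seed = 33)
  weak <- gen_competition(n_lines = 40, s = 0.04, mutation_rate_beneficial = 2e-7,
                          n_transfers = 60, seed = 33)
  med <- function(x) stats::median(x$truth$fixation_generation, na.rm = TRUE)
  expect_lt(med(strong), med(weak))
  expect_error(gen_competition(bottleneck_size = 5), ">= 10")
})

test_that("fitness-matrix generator produces the requested group structure", {
  fm <- gen_fitness_matrix(n_clones_per_group = c(4, 6), n_conditions = 5,
                           sigma_interaction = c(0.1, 0.01), seed = 12)
  expect_equal(length(unique(fm$fitness$strain)), 10)
  expect_equal(length(unique(fm$fitness$condition)), 5)
  expect_equal(nrow(fm$fitness), 10 * 5 * 3)
  # the high-interaction group really has larger clone-by-condition spread
  mats <- lapply(split(fm$fitness, fm$fitness$group), fitness_matrix)
  spread <- vapply(mats, function(m) {
    mean(apply(sweep(m, 2, colMeans(m)), 2, stats::var))
  }, numeric(1))
  expect_gt(spread[["group1"]], spread[["group2"]])

  # degenerate case: no interaction, no replicate noise -> clones identical
  # within group up to main effects; zero-variance columns are refused by
  # the distance step only when truly flat
  fm0 <- gen_fitness_matrix(n_clones_per_group = c(3, 3), n_conditions = 4,
                            sigma_interaction = c(0, 0), sigma_replicate = 0,
                            sigma_clone = 0, seed = 12)
  m0 <- fitness_matrix(split(fm0$fitness, fm0$fitness$group)$group1)
  expect_error(condition_distance_matrix(m0), "zero-variance")
})

test_that("variant generator plants filters-boundary records that strict filters drop", {
  va <- gen_variants_and_annotation(n_clones = 4, seed = 21)
  for (cl in names(va$clones)) {
    kept <- filter_variants(va$clones[[cl]])
    kept_keys <- paste(kept$chromosome, kept$position, kept$alt, sep = ":")
    expect_false(any(va$truth$boundary_keys %in% kept_keys))
  }
})
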
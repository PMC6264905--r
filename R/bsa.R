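#' Assign F1 spores to good and bad pools
#'
#' Implements the pool rules of bulk segregant mapping from backcrossed
#' tetrads: only four-viable-spore tetrads are used; a spore qualifies for
#' the "good" pool if its fitness is within `tolerance` of the evolved
#' reference and strictly closer to it than to the ancestral reference
#' (symmetrically for "bad"); at most one good and one bad spore (the
#' closest qualifier of each kind) is taken per tetrad; tetrads in which no
#' spore resembles either parent contribute nothing.
#'
#' @param spores Data frame with columns `tetrad`, `spore` and `fitness`
#'   (the decisive assay condition, already chosen per clone).
#' @param evolved_ref,ancestral_ref Reference fitness of the evolved and
#'   ancestral parent (must differ).
#' @param tolerance Maximal absolute deviation from a reference for a spore
#'   to count as similar; defaults to half the gap between the references.
#' @param max_pool_size If non-`NULL`, each pool is trimmed to the
#'   qualifiers closest to its reference (sequenced pools held 5-20 spores).
#' @return List with character vectors `good_pool` and `bad_pool` of spore
#'   ids, plus the per-spore assignment table `table`.
#' @export
assign_pools <- function(spores, evolved_ref, ancestral_ref,
                         tolerance = NULL, max_pool_size = NULL) {
  need <- c("tetrad", "spore", "fitness")
  if (!all(need %in% names(spores))) {
    stop("spore table needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  stop_if_not_scalar_number(evolved_ref, "evolved_ref")
  stop_if_not_scalar_number(ancestral_ref, "ancestral_ref")
  if (evolved_ref == ancestral_ref) {
    stop("evolved and ancestral references must be distinct", call. = FALSE)
  }
  if (is.null(tolerance)) tolerance <- 0.5 * abs(evolved_ref - ancestral_ref)
  if (tolerance <= 0) stop("'tolerance' must be positive", call. = FALSE)

  sizes <- table(spores$tetrad)
  bad_tetrads <- names(sizes)[sizes != 4L]
  if (length(bad_tetrads) > 0L) {
    warning("rejecting tetrad(s) without exactly 4 viable spores: ",
            paste(bad_tetrads, collapse = ", "))
    spores <- spores[!spores$tetrad %in% bad_tetrads, , drop = FALSE]
  }

  spores$dist_evolved <- abs(spores$fitness - evolved_ref)
  spores$dist_ancestral <- abs(spores$fitness - ancestral_ref)
  spores$pool <- NA_character_

  for (tid in unique(spores$tetrad)) {
    idx <- which(spores$tetrad == tid)
    de <- spores$dist_evolved[idx]
    da <- spores$dist_ancestral[idx]
    good_ok <- de <= tolerance & de < da
    bad_ok <- da <= tolerance & da < de
    if (any(good_ok)) {
      spores$pool[idx[which(good_ok)[which.min(de[good_ok])]]] <- "good"
    }
    if (any(bad_ok)) {
      spores$pool[idx[which(bad_ok)[which.min(da[bad_ok])]]] <- "bad"
    }
  }

  good <- spores[!is.na(spores$pool) & spores$pool == "good", , drop = FALSE]
  bad <- spores[!is.na(spores$pool) & spores$pool == "bad", , drop = FALSE]
  if (!is.null(max_pool_size)) {
    if (nrow(good) > max_pool_size) {
      good <- good[order(good$dist_evolved)[seq_len(max_pool_size)], , drop = FALSE]
    }
    if (nrow(bad) > max_pool_size) {
      bad <- bad[order(bad$dist_ancestral)[seq_len(max_pool_size)], , drop = FALSE]
    }
    spores$pool[!(spores$spore %in% c(good$spore, bad$spore))] <- NA_character_
  }
  list(good_pool = good$spore, bad_pool = bad$spore,
       table = spores[, c("tetrad", "spore", "fitness", "pool")])
}

#' Simulate the null distribution of a pool's observed allele frequency
#'
#' Null model for a locus unlinked to the selected phenotype: the number of
#' mutant spores in a pool of N segregants is Binomial(N, 1/2) (Mendelian
#' 2:2 segregation), and sequencing reads then sample the pooled DNA as
#' Binomial(coverage, k/N) under equimolar per-spore contribution. The
#' observed frequency is reads/coverage.
#'
#' @param pool_size Number of spores N in the pool (>= 1).
#' @param coverage Sequencing depth at the locus (>= 1).
#' @param reps Number of Monte-Carlo replicates.
#' @param seed Optional integer seed (RNG state is restored afterwards).
#' @return Numeric vector of `reps` simulated observed allele frequencies.
#' @export
simulate_null_pool_freq <- function(pool_size, coverage, reps = 10000, seed = NULL) {
  stop_if_not_scalar_number(pool_size, "pool_size", positive = TRUE)
  stop_if_not_scalar_number(coverage, "coverage", positive = TRUE)
  stop_if_not_scalar_number(reps, "reps", positive = TRUE)
  with_seed(seed, {
    k <- stats::rbinom(reps, size = pool_size, prob = 0.5)
    reads <- stats::rbinom(reps, size = coverage, prob = k / pool_size)
    reads / coverage
  })
}

#' Monte-Carlo null thresholds for pool allele frequencies
#'
#' For each pool size, simulates the null distribution of the single-pool
#' observed allele frequency and of the difference between two independent
#' pools (good minus bad), and reports upper percentiles of each. These
#' percentiles calibrate the strong-effect criteria used by
#' [classify_strong_effect()].
#'
#' @param pool_sizes Integer vector of pool sizes N.
#' @param coverage Sequencing depth (default 200, the pool sequencing depth).
#' @param reps Monte-Carlo replicates per pool size (default 10,000).
#' @param percentiles Upper percentiles to report (default 90, 95, 99).
#' @param seed Optional integer seed.
#' @return Data frame with columns `pool_size`, `percentile`,
#'   `single_pool_threshold`, `difference_threshold`.
#' @export
null_thresholds <- function(pool_sizes, coverage = 200, reps = 10000,
                            percentiles = c(90, 95, 99), seed = NULL) {
  if (length(pool_sizes) == 0L || any(pool_sizes < 1)) {
    stop("'pool_sizes' must be positive integers", call. = FALSE)
  }
  with_seed(seed, {
    out <- lapply(pool_sizes, function(N) {
      single <- simulate_null_pool_freq(N, coverage, reps)
      good <- simulate_null_pool_freq(N, coverage, reps)
      bad <- simulate_null_pool_freq(N, coverage, reps)
      data.frame(
        pool_size = N,
        percentile = percentiles,
        single_pool_threshold = unname(stats::quantile(single, percentiles / 100)),
        difference_threshold = unname(stats::quantile(good - bad, percentiles / 100))
      )
    })
    do.call(rbind, out)
  })
}

#' Classify strong-effect mutations from pool-seq frequencies
#'
#' A locus is selected as carrying a strong-effect mutation if (1) its
#' allele frequency in the good spore pool is greater than `thr_good`
#' (default 0.70), or (2) the difference between good- and bad-pool
#' frequencies is greater than `thr_diff` (default 0.45). Both inequalities
#' are strict. The defaults are the working criteria anchored to the
#' simulated null at pool size 9 and coverage 200.
#'
#' @param table Data frame with per-locus counts `good_alt`, `good_depth`,
#'   `bad_alt`, `bad_depth` (frequencies are derived), or precomputed
#'   `good_freq`/`bad_freq` columns. A `locus` column is carried through.
#' @param thr_good Good-pool frequency threshold in (0, 1).
#' @param thr_diff Good-minus-bad difference threshold in (0, 1).
#' @return The input with added columns `good_freq`, `bad_freq`, `selected`
#'   (logical) and `criterion` (`"good_pool"`, `"difference"`, `"both"` or
#'   `NA`). Loci with zero depth in either pool are dropped with a warning.
#' @export
classify_strong_effect <- function(table, thr_good = 0.70, thr_diff = 0.45) {
  if (thr_good <= 0 || thr_good >= 1 || thr_diff <= 0 || thr_diff >= 1) {
    stop("thresholds must lie in (0, 1)", call. = FALSE)
  }
  tab <- as.data.frame(table)
  has_counts <- all(c("good_alt", "good_depth", "bad_alt", "bad_depth") %in% names(tab))
  if (has_counts) {
    zero <- tab$good_depth == 0 | tab$bad_depth == 0
    if (any(zero)) {
      warning("skipping ", sum(zero), " locus/loci with zero depth")
      tab <- tab[!zero, , drop = FALSE]
    }
    if (any(tab$good_alt > tab$good_depth | tab$bad_alt > tab$bad_depth)) {
      stop("alt read count exceeds depth", call. = FALSE)
    }
    tab$good_freq <- tab$good_alt / tab$good_depth
    tab$bad_freq <- tab$bad_alt / tab$bad_depth
  } else if (!all(c("good_freq", "bad_freq") %in% names(tab))) {
    stop("table needs good/bad alt+depth counts or good_freq/bad_freq columns",
         call. = FALSE)
  }
  c1 <- tab$good_freq > thr_good
  c2 <- (tab$good_freq - tab$bad_freq) > thr_diff
  tab$selected <- c1 | c2
  tab$criterion <- ifelse(c1 & c2, "both",
                          ifelse(c1, "good_pool",
                                 ifelse(c2, "difference", NA_character_)))
  tab
}
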
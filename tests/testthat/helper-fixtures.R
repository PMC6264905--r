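# Small fixture builders shared across test files.

# logistic OD trajectory sampled every `interval` minutes
logistic_od <- function(times_min, r_per_hour, K = 1, od0 = 0.1) {
  th <- times_min / 60
  K * od0 * exp(r_per_hour * th) / (K + od0 * (exp(r_per_hour * th) - 1))
}

# exact CDF of the observed pool allele frequency under the null:
# k ~ Binomial(N, 1/2) mutant spores, reads ~ Binomial(coverage, k/N).
# Independent of the package's Monte-Carlo path.
null_pool_freq_cdf <- function(x, N, coverage) {
  k <- 0:N
  w <- stats::dbinom(k, N, 0.5)
  vapply(x, function(xi) {
    sum(w * stats::pbinom(floor(xi * coverage), coverage, k / N))
  }, numeric(1))
}

# smallest frequency f (on the reads/coverage grid) with CDF >= p
null_pool_freq_quantile <- function(p, N, coverage) {
  grid <- (0:coverage) / coverage
  cdf <- null_pool_freq_cdf(grid, N, coverage)
  grid[which(cdf >= p)[1]]
}

# seeded evaluation helper for property loops
with_seed_test <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  code
}
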
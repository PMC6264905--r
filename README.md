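# hubevolve

Statistical toolkit for **hub-gene replacement evolution experiments** in
budding yeast — the design in which an essential network hub (here Hsp90) is
swapped for a distant ortholog and replicate populations are evolved by
daily serial transfer. It is written for experimental-evolution labs that
need the full computational chain behind such a study, reproducible and
testable end-to-end without any external download:

* **Growth fitness** — maximal growth rate of a plate-reader OD595 curve as
  the maximum 10-point sliding-window least-squares slope (OD595/hour);
  fitness improvement `(F_x/F_a − 1) × 100%`; one-tailed Welch and paired
  *t* tests; Benjamini–Hochberg correction.
* **Competition dynamics** — fixation calls on two-color subpopulation
  trajectories (first sampled crossing of 95%, either color), generations
  per transfer `log2(dilution)`, effective size `N_e = N_0 × g`.
* **Phenotype divergence** — per-condition mean normalization, hierarchical
  clustering, centered PCA, Pearson correlation distances `d = 1 − r`
  between conditions, and two one-tailed group tests (pooled-distance
  Wilcoxon; paired *t* on per-condition improvement variances).
* **Bulk segregant mapping** — good/bad spore-pool assignment rules from
  backcrossed tetrads, a seeded Monte-Carlo null for pooled-sequencing
  allele frequencies (`Bin(N, 1/2)` spores, `Bin(coverage, k/N)` reads),
  percentile thresholds, and strong-effect classification
  (good-pool frequency > 70% **or** good−bad difference > 45%).
* **Variant filters** — depth/frequency filtering (>20×, >35%), ancestor
  subtraction with overlapping-ORF collapse and shared-variant exclusion,
  median-normalized gene copy number with a 0.8 change cutoff, and the
  per-bp per-generation mutation rate.
* **Enrichment** — hypergeometric over-representation of gene categories
  with enrichment score `(k/n)/(K/N)` and BH correction.
* **Synthetic data** — seeded generators for every input above (logistic
  growth curves, Wright–Fisher serial-transfer competitions, 2:2
  segregating tetrads, binomial pool sequencing, strain×condition fitness
  matrices, variant cohorts with planted signals), each shipping a truth
  record for parameter-recovery testing.

## Worked example

Estimate a well's fitness, compare it to an ancestor, and map planted
causal loci in a simulated backcross:

```r
library(hubevolve)

g  <- gen_growth_curves(n_wells = 2, rate_range = c(0.25, 0.35),
                        noise_sd = 0.005, seed = 8)
fv <- max_growth_rate(g$curves[[1]])
fv
#> <fitness_value> well01 / synthetic (rep 1): 0.0790 OD595/h (window at 440 min)
fitness_improvement(fv, max_growth_rate(g$curves[[2]]))
#>   strain_id condition improvement_percent
#> 1    well01 synthetic            10.48029

null_thresholds(9, coverage = 200, reps = 10000, seed = 1)
#>  pool_size percentile single_pool_threshold difference_threshold
#>          9         90                  0.72                0.315
#>          9         95                  0.78                0.400
#>          9         99                  0.89                0.560

td  <- gen_tetrads(n_tetrads = 40, seed = 4001)
pa  <- assign_pools(td$spores, td$evolved_ref, td$ancestral_ref, max_pool_size = 9)
ps  <- gen_poolseq(pa, td$genotypes, coverage = 200, seed = 4101)
cls <- classify_strong_effect(ps)
cls[cls$selected, c("locus", "good_freq", "bad_freq", "criterion")]
#>       locus good_freq bad_freq criterion
#>   causal_01     1.000    0.000      both
#>   causal_02     1.000    0.000      both
#>   causal_03     1.000    0.000      both
#>  neutral_12     0.725    0.545 good_pool
#>  neutral_18     0.890    0.755 good_pool
#>  neutral_19     0.735    0.635 good_pool
```

The maximal windowed rate (0.079 OD/h here, against a true inflection slope
of 0.074 for this well's generating logistic) is the well's fitness value;
the improvement is the percent rate gain over the ancestor well. The
threshold table gives the Monte-Carlo null percentiles at pool size 9 and
coverage 200 — note that the 70% working criterion sits at the null's 90th
percentile, which is why all three planted causal loci are recovered at
frequency 1.0 while a few unlinked neutral loci also clear the bar (the
criteria favour sensitivity; see the methods vignette for the quantified
false-positive rate). `run_pipeline(seed = 1, out_dir = "demo/")` runs every
stage on synthetic data and writes a manifest of all applied thresholds.

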
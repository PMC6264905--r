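---
title: "Methods: fitness, divergence and mapping statistics for hub-replacement evolution experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fitness, divergence and mapping statistics for hub-replacement evolution experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hubevolve)
```

## The experimental design this package models

A hub-replacement evolution experiment swaps an essential, highly connected
gene — here the chaperone Hsp90 of *Saccharomyces cerevisiae* — for a distant
ortholog, and then lets replicate populations adapt under serial transfer.
The computational questions that follow are the ones this package answers:

1. How fit is a strain? (maximal growth rate from a plate-reader OD curve)
2. When did a beneficial mutation sweep? (two-color competition trajectories)
3. How phenotypically divergent are the evolved clones? (normalization,
   clustering, PCA, Pearson correlation distances, and two group tests)
4. Which mutations have strong fitness effects? (bulk segregant mapping with
   a simulated null)
5. Which variants are genuinely evolved mutations, and what functions do
   they hit?
   (ancestor subtraction, exclusion rules, copy number, GO-style enrichment)

Every stage also has a seeded generator (`gen_*`) that produces synthetic
inputs with the statistical structure the stage assumes, so the whole
pipeline runs and is tested without any external data.

## Growth-rate estimation

Wells start at OD595 0.1 and are read every 10 minutes. The fitness value of
a well is the **maximal 10-point sliding-window slope** of OD against time in
hours (OD595/hour): one ordinary least-squares slope per contiguous window,
stride 1, maximum over windows, ties to the earliest window. We use raw OD
(not log OD) because rates are reported in OD595/hour, implying a linear OD
slope; a `log_od` flag provides the exponential-phase specific rate, and an
`endpoint` method replaces the regression slope with the window's endpoint
difference for sensitivity analysis. Windows containing missing readings are
skipped, never imputed. No baseline subtraction is applied by default;
truncation at the diauxic shift is the data producer's responsibility (an
`od_ceiling` flag is available).

For a logistic curve with rate $r$ and capacity $K$ the analytic maximal
slope is $rK/4$ at the inflection point. On noiseless sampled curves the
10-point window recovers this within 2% (the window averages the derivative
over ±45 minutes, a relative bias of $\approx (r^2/12)\,\Sigma x^4/\Sigma
x^2$, about 0.5% at $r = 0.4\,h^{-1}$). With realistic reading noise
(sd 0.005 OD) the estimator remains strongly rank-faithful (correlation with
$rK/4$ above 0.99 in our tests) but the *maximum over ~400 overlapping noisy
windows* is upward-biased by one to two slope standard errors
($0.005/\sqrt{\Sigma x_c^2} \approx 0.0033$ OD/h), which is material for
slow growers; absolute accuracy claims on noisy data should therefore be
made on replicate means, as the experimental design does ($N \ge 3$).

Fitness improvement is $(F_x/F_a - 1) \times 100\%$ against the ancestor
measured in the same condition. Group comparisons use the one-tailed Welch
$t$ (unequal variances, Welch–Satterthwaite df) and the one-tailed paired
$t$ (df = pairs − 1); `bh_adjust()` applies Benjamini–Hochberg step-up
correction. A Shapiro–Wilk utility is provided for reporting only and never
gates a computation.

## Serial transfer and fixation calls

A daily 1,000-fold dilution corresponds to $\log_2 1000 = 9.966$ generations
per transfer, and the effective population size of the regime is
$N_e = N_0 \times g$ with $N_0$ the bottleneck size. Fixation of a
two-color competition culture is called at the **first sampled generation at
which either color exceeds 95% frequency** — strictly greater, on sampled
points only (flow-cytometry time points are discrete; we do not
interpolate). The first crossing is reported even if the trajectory later
dips back (a `sustained` mode requires persistence). Either color may fix;
the call records which.

The simulator (`gen_competition`) grows each culture deterministically from
the bottleneck to $N_0 \times$ dilution in ~10 doubling steps, seeds
beneficial mutants Poisson-wise on each color background per division as
growth proceeds (so early mutations expand before the bottleneck), applies a
per-generation fitness weight $1+s$ to mutants, and bottlenecks by
multinomial sampling — the standard serial-transfer approximation with drift
concentrated at the dilution. Defaults: $N_0 = 4.7\times10^4$ (the first
regime phase), $s = 0.08$ and a beneficial rate of $10^{-7}$ per division,
chosen once as plausible for a strongly maladapted starting genotype; under
them roughly half of lines fix within 450 generations. With $s = 0$ and no
mutation the color frequency is a martingale, which the tests verify over
1,000 replicates.

## Phenotypic divergence

Fitness matrices are strain × condition tables of replicate-mean maximal
rates. For clustering, values are divided by the per-condition mean (unit
column means); `hclust`-style agglomeration uses Euclidean distance and
complete linkage by default (both configurable). PCA is run on raw fitness
values, column-centered and unscaled. The phenotypic distance between two
conditions is $d = 1 - r$, the Pearson correlation distance across clones:
small $d$ means clones rank the same way in both conditions.

Two group-level divergence statistics are provided:

* `divergence_test()` pools each group's $\binom{11}{2} = 55$ upper-triangle
  condition distances and applies a one-tailed Wilcoxon rank-sum test
  (group 1 greater). **Caveat we quantify rather than hide:** the 55
  distances within a group are computed from the same clones and are
  mutually dependent, so the rank-sum null variance is understated; with a
  clone main-effect component in the data the measured type-I error at
  $\alpha = 0.05$ is ~0.25 rather than 0.05. The test is faithful to the
  published procedure and has high power (≥ 0.93 at a 3:1 interaction-
  variance ratio in our simulations), but its p-values should be read as
  descriptive rather than exact.
* `improvement_variance_test()` compares the per-condition variances of
  clone improvements between groups with a one-tailed paired $t$ across
  conditions. Because the 11 condition variances are nearly independent,
  this test calibrates well (measured null rejection 0.06–0.09) and reaches
  full power at the same 3:1 ratio.

The generator behind these checks (`gen_fitness_matrix`) draws value =
condition baseline + clone main effect + clone×condition interaction +
replicate noise, with the interaction sd set per group (defaults 0.06 vs
0.02 OD/h on a 0.35 baseline — a 3:1 divergence signal — with clone main sd
0.02, replicate sd 0.01, 9 vs 11 clones, 11 conditions, 3 replicates,
matching the scale of the experimental design). What it does not emulate:
condition-specific measurement error, correlated stress responses between
chemically similar conditions, and non-Gaussian fitness outliers — passing
tests show correct statistical behaviour under the stated model, not
robustness to those features of real data.

## Bulk segregant mapping

Backcrossed tetrads contribute only if all four spores are viable. A spore
joins the **good pool** if its fitness is within a tolerance of the evolved
parent's and strictly closer to it than to the ancestor's (symmetrically for
the **bad pool**); at most one of each per tetrad, the closest qualifier
winning; tetrads resembling neither parent contribute nothing. Published
protocols state no numeric similarity rule, so the tolerance defaults to
half the parental gap (configurable), and pools can be capped at the sequenced size
(5–20 spores; 9 in the acceptance analyses) keeping the closest qualifiers.

The null for an unlinked locus is Mendelian: $k \sim \mathrm{Bin}(N, 1/2)$
mutant spores in a pool of $N$, then reads $\sim \mathrm{Bin}(c, k/N)$ at
coverage $c$ under equimolar per-spore DNA contribution; good and bad pools
are simulated independently. `null_thresholds()` reports the 90/95/99th
Monte-Carlo percentiles (10,000 replicates, seeded) of the single-pool
frequency and of the good-minus-bad difference for pool sizes 5, 9, 10, 18
and 21 at coverage 200; the tests verify every percentile against the exact
binomial-mixture CDF to ±0.01. At $N = 9$ the exact single-pool percentiles
are 0.715/0.785/0.890 and the difference percentiles ≈ 0.31/0.40/0.56, so
the working criteria — **good-pool frequency > 70% or good−bad difference >
45%**, both strict — sit at/within the 90th–99th percentile band.

A consequence worth stating plainly: because 0.70 is essentially the null's
90th percentile, an unlinked neutral locus passes the criteria with
probability ≈ 0.12 (exactly 0.1125 for the single-pool arm; ≥ 0.09 =
$P(k \ge 7)$ even at infinite coverage). The criteria are designed for
sensitivity on a handful of candidate loci, not for genome-wide specificity;
with ~20 scored loci, two false positives are expected, and no pool size of
9 can push the per-locus false-positive rate below ~9%. Planted causal loci
with relative effects ≥ 0.12 are recovered in 100% of simulated crosses
(40 tetrads, pools of 9, coverage 200, defaults chosen to mirror that
design).

## Variant filtering, copy number, mutation rate

Variant records are kept when depth > 20 and allele frequency > 35% (strict,
per the calling rules; the frequency floor drops to 10% for segregant
pools). Evolved mutations are clone variants absent from the ancestor, with
two exclusions: same-site records double-called in two overlapping ORFs are
collapsed into one (gene labels joined), and variants shared by ≥ 2 evolved
clones are flagged as pre-existing standing variation and set aside for
audit. Copy number is per-gene mean coverage over the genome-wide median
coverage; a gene is flagged when evolved and ancestral copy numbers differ
by more than 0.8 (strict). The mutation rate is total mutations /(clones ×
genome bp × generations); genome size and generation count are explicit
inputs because published rates depend on those conventions.

## Enrichment

For a query of mutated genes (set semantics; dubious/uncharacterized ORFs
excludable) each category's enrichment score is $(k/n)/(K/N)$ and its
p-value the exact upper-tail hypergeometric $P(X \ge k)$, BH-corrected
across tested categories; single-gene categories are excluded. The genome
background annotation is always an input file — published category tables
depend on the annotation snapshot used, so exact reproduction of any
specific table is not a test target; calibration and planted-category
recovery are verified on packaged synthetic annotations (a 30-gene category
at 10× over-representation ranks first and significant in ≥ 95% of runs;
uniformly random queries yield essentially no BH-significant categories).

## Reproducibility machinery

All stochastic functions accept an explicit seed and restore the caller's
RNG state. `run_pipeline()` executes the full synthetic demonstration in
dependency order, writes every stage output as TSV/JSON into a fresh run
directory, and emits a manifest recording the package version, root seed,
per-stage parameters, every threshold actually applied (window 10, fixation
0.95, depth 20 / frequency 35, CNV 0.8, pool criteria 0.70/0.45, α 0.05)
and MD5 digests of the outputs; reruns with the same seed are byte-identical.

Problem sizes used by the test-suite and the acceptance script — 10,000
Monte-Carlo replicates per pool size, 100 simulated crosses, 200 calibration
and power runs per divergence statistic, 1,000 neutral drift replicates,
50-well growth panels — were chosen as the sizes the corresponding analyses
use in practice, and run in well under a minute in total.

## Known limitations

* Loci assort independently in the tetrad generator; linkage and
  recombination maps are out of scope, so mapping resolution along a
  chromosome is not modelled.
* The pooled-distance Wilcoxon inherits the dependence problem described
  above; a permutation-based alternative would calibrate better but would
  no longer be the published procedure.
* Reproducing the source study's numerical tables requires its
  supplementary data, which are spreadsheets we cannot redistribute; the
  corresponding checks document a plain-text drop-in layout
  (`?load_supplementary`) and run whenever those files are provided.
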
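#' Filter variant records by depth and allele frequency
#'
#' Keeps records whose read depth is strictly greater than `min_depth` and
#' whose allele frequency (in percent) is strictly greater than
#' `min_freq_percent`. Defaults match the evolved-clone calling thresholds
#' (depth > 20, frequency > 35); for segregant pools the frequency floor is
#' typically lowered to 10 to retain low-frequency evolved alleles.
#'
#' @param records Data frame with numeric columns `depth` and `allele_freq`
#'   (percent, 0-100).
#' @param min_depth Depth threshold (strict).
#' @param min_freq_percent Frequency threshold in percent (strict).
#' @return The retained records.
#' @export
filter_variants <- function(records, min_depth = 20, min_freq_percent = 35) {
  if (!all(c("depth", "allele_freq") %in% names(records))) {
    stop("records need 'depth' and 'allele_freq' columns", call. = FALSE)
  }
  if (any(records$allele_freq < 0 | records$allele_freq > 100, na.rm = TRUE)) {
    stop("'allele_freq' must be a percent in [0, 100]", call. = FALSE)
  }
  records[records$depth > min_depth & records$allele_freq > min_freq_percent, ,
          drop = FALSE]
}

variant_key <- function(records) {
  paste(records$chromosome, records$position, records$alt, sep = ":")
}

#' Call evolved mutations by comparison with the ancestor
#'
#' An evolved mutation is a variant present in an evolved clone but absent
#' from the ancestral clone at the same chromosome/position/alternate
#' allele. Two further exclusion rules are applied: (a) records of the same
#' clone called twice at one site because the site overlaps two open
#' reading frames are collapsed into a single record (gene labels joined);
#' (b) variants present in `panshared_min_clones` or more evolved clones are
#' flagged as putatively pre-existing in the ancestral population and
#' excluded from the mutation table (but returned for audit).
#'
#' @param evolved_by_clone Named list of per-clone variant data frames, each
#'   with columns `chromosome`, `position`, `ref`, `alt` and optionally
#'   `gene`, `effect`, `depth`, `allele_freq`.
#' @param ancestor Ancestral variant data frame with the same coordinate
#'   columns.
#' @param panshared_min_clones Minimum number of clones sharing a variant
#'   for it to be treated as pre-existing (default 2).
#' @return List with `mutations` (data frame with a `clone` column) and
#'   `preexisting` (the excluded shared variants).
#' @export
call_evolved_mutations <- function(evolved_by_clone, ancestor,
                                   panshared_min_clones = 2L) {
  if (is.null(names(evolved_by_clone)) || any(names(evolved_by_clone) == "")) {
    stop("'evolved_by_clone' must be a named list of clone variant tables",
         call. = FALSE)
  }
  anc_keys <- variant_key(ancestor)
  # process clones in a fixed (sorted) order so output is order-independent
  clones <- sort(names(evolved_by_clone))
  per_clone <- lapply(clones, function(cl) {
    rec <- as.data.frame(evolved_by_clone[[cl]])
    rec <- rec[!(variant_key(rec) %in% anc_keys), , drop = FALSE]
    if (nrow(rec) == 0L) return(rec)
    # collapse double calls at one site annotated to two overlapping ORFs
    key <- variant_key(rec)
    if (anyDuplicated(key)) {
      first <- !duplicated(key)
      if ("gene" %in% names(rec)) {
        genes <- vapply(split(as.character(rec$gene), key), function(g) {
          paste(unique(g), collapse = ";")
        }, character(1))
        rec$gene[first] <- genes[key[first]]
      }
      rec <- rec[first, , drop = FALSE]
    }
    rec$clone <- cl
    rec
  })
  all_rec <- do.call(rbind, per_clone)
  if (is.null(all_rec) || nrow(all_rec) == 0L) {
    return(list(mutations = all_rec, preexisting = all_rec))
  }
  key <- variant_key(all_rec)
  n_clones_sharing <- vapply(split(all_rec$clone, key),
                             function(cl) length(unique(cl)), integer(1))
  shared <- key %in% names(n_clones_sharing)[n_clones_sharing >= panshared_min_clones]
  rownames(all_rec) <- NULL
  list(mutations = all_rec[!shared, , drop = FALSE],
       preexisting = all_rec[shared, , drop = FALSE])
}

#' Per-gene copy number from read coverage
#'
#' Copy number of a gene is its mean read coverage normalized by the median
#' of whole-genome coverage.
#'
#' @param per_gene_coverage Data frame with columns `gene` and `mean_cov`.
#' @param genome_median_coverage Median genome-wide coverage (> 0).
#' @return Data frame with `gene`, `mean_cov` and `normalized_cn`.
#' @export
gene_copy_number <- function(per_gene_coverage, genome_median_coverage) {
  if (!all(c("gene", "mean_cov") %in% names(per_gene_coverage))) {
    stop("coverage table needs 'gene' and 'mean_cov' columns", call. = FALSE)
  }
  stop_if_not_scalar_number(genome_median_coverage, "genome_median_coverage",
                            positive = TRUE)
  out <- per_gene_coverage
  out$normalized_cn <- out$mean_cov / genome_median_coverage
  out
}

#' Flag copy-number changes relative to the ancestor
#'
#' A gene is flagged when the absolute difference between its normalized
#' copy number in the evolved and ancestral strain is strictly greater than
#' `delta` (default 0.8).
#'
#' @param evolved,ancestor Data frames from [gene_copy_number()] sharing the
#'   same genes.
#' @param delta Copy-number difference threshold (strict).
#' @return Data frame with `gene`, `cn_evolved`, `cn_ancestor`, `cn_change`
#'   and logical `flagged`.
#' @export
flag_cnv <- function(evolved, ancestor, delta = 0.8) {
  m <- merge(evolved[, c("gene", "normalized_cn")],
             ancestor[, c("gene", "normalized_cn")],
             by = "gene", suffixes = c("_evolved", "_ancestor"))
  if (nrow(m) == 0L) stop("no genes shared between evolved and ancestor", call. = FALSE)
  data.frame(
    gene = m$gene,
    cn_evolved = m$normalized_cn_evolved,
    cn_ancestor = m$normalized_cn_ancestor,
    cn_change = m$normalized_cn_evolved - m$normalized_cn_ancestor,
    flagged = abs(m$normalized_cn_evolved - m$normalized_cn_ancestor) > delta
  )
}

#' Per-base-pair per-generation mutation rate
#'
#' rate = total_mutations / (n_clones x genome_size_bp x generations).
#'
#' @param total_mutations Total mutations counted across clones (>= 0).
#' @param n_clones Number of sequenced clones (> 0).
#' @param genome_size_bp Callable genome size in base pairs (> 0).
#' @param generations Generations elapsed during the evolution (> 0).
#' @return Mutation rate per bp per generation.
#' @export
mutation_rate <- function(total_mutations, n_clones, genome_size_bp, generations) {
  if (!is.numeric(total_mutations) || total_mutations < 0) {
    stop("'total_mutations' must be a non-negative count", call. = FALSE)
  }
  stop_if_not_scalar_number(n_clones, "n_clones", positive = TRUE)
  stop_if_not_scalar_number(genome_size_bp, "genome_size_bp", positive = TRUE)
  stop_if_not_scalar_number(generations, "generations", positive = TRUE)
  total_mutations / (n_clones * genome_size_bp * generations)
}

#' Read a variant table from a VCF file
#'
#' Convenience reader converting a VCF (with per-sample DP and AF or AD
#' fields) into the flat variant-record layout used by [filter_variants()]
#' and [call_evolved_mutations()]. Requires the `vcfR` package.
#'
#' @param path Path to an (uncompressed or gzipped) VCF 4.x file.
#' @param sample Sample name; defaults to the first sample.
#' @return Data frame with columns `chromosome`, `position`, `ref`, `alt`,
#'   `depth`, `allele_freq` (percent).
#' @export
read_variants_vcf <- function(path, sample = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the 'vcfR' package", call. = FALSE)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  dp <- vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)
  if (is.null(sample)) sample <- colnames(dp)[1]
  af <- tryCatch(vcfR::extract.gt(v, element = "AF", as.numeric = TRUE),
                 error = function(e) NULL)
  if (is.null(af)) {
    ad <- vcfR::extract.gt(v, element = "AD")
    alt_reads <- as.numeric(vapply(strsplit(ad[, sample], ","), `[`, "", 2))
    freq <- 100 * alt_reads / dp[, sample]
  } else {
    freq <- 100 * af[, sample]
  }
  data.frame(
    chromosome = fix$CHROM,
    position = as.integer(fix$POS),
    ref = fix$REF,
    alt = fix$ALT,
    depth = dp[, sample],
    allele_freq = freq
  )
}
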
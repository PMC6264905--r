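#' Construct a gene-category annotation set
#'
#' @param memberships Data frame with columns `gene` and `category`, one row
#'   per membership (a gene may belong to several categories).
#' @param genome_genes Character vector of all genes in the genome
#'   background; defaults to the genes appearing in `memberships`. Every
#'   annotated gene must belong to the background.
#' @return List of class `annotation_set` with `genome_genes` and
#'   `categories` (named list of gene vectors).
#' @export
annotation_set <- function(memberships, genome_genes = NULL) {
  if (!all(c("gene", "category") %in% names(memberships))) {
    stop("memberships need 'gene' and 'category' columns", call. = FALSE)
  }
  memberships$gene <- as.character(memberships$gene)
  memberships$category <- as.character(memberships$category)
  if (is.null(genome_genes)) {
    genome_genes <- unique(memberships$gene)
  }
  genome_genes <- unique(as.character(genome_genes))
  missing <- setdiff(memberships$gene, genome_genes)
  if (length(missing) > 0L) {
    stop("annotated gene(s) absent from genome background: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  cats <- lapply(split(memberships$gene, memberships$category), unique)
  structure(list(genome_genes = genome_genes, categories = cats),
            class = "annotation_set")
}

#' GO-style enrichment score
#'
#' Ratio of the query proportion to the background proportion:
#' (k/n) / (K/N), where k of the n query genes and K of the N genome genes
#' belong to the category.
#'
#' @param k Query genes in the category.
#' @param n Query size.
#' @param K Category size in the genome.
#' @param N Genome background size.
#' @return The enrichment score.
#' @export
enrichment_score <- function(k, n, K, N) {
  if (K == 0) stop("category has no genes in the background (K = 0)", call. = FALSE)
  if (n <= 0 || n > N || k < 0 || k > min(n, K) || K > N) {
    stop("invalid (k, n, K, N) combination", call. = FALSE)
  }
  (k / n) / (K / N)
}

#' Upper-tail hypergeometric p-value
#'
#' P(X >= k) where X counts category genes among n draws without
#' replacement from a genome of N genes of which K are in the category —
#' the over-representation test.
#'
#' @inheritParams enrichment_score
#' @return Exact upper-tail probability.
#' @export
hypergeom_pvalue <- function(k, n, K, N) {
  if (n < 0 || n > N || K < 0 || K > N || k < 0 || k > min(n, K)) {
    stop("invalid (k, n, K, N) combination", call. = FALSE)
  }
  stats::phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
}

#' Category enrichment among a set of mutated genes
#'
#' Tests each annotation category for over-representation in the query via
#' the upper-tail hypergeometric test, with Benjamini-Hochberg correction
#' across tested categories. Genes in `exclusions` (e.g. dubious or
#' uncharacterized ORFs) are removed from the query first; categories with
#' a single annotated gene are not tested; query genes hit by several
#' mutations count once (set semantics).
#'
#' @param query_genes Character vector of mutated genes.
#' @param annotation An [annotation_set()].
#' @param exclusions Genes to drop from the query before testing.
#' @param alpha Adjusted-p significance level (default 0.05).
#' @return Data frame sorted by raw p with columns `category`, `genes`
#'   (semicolon-joined hits), `k`, `n`, `K`, `N`, `score`, `p_raw`,
#'   `p_adjusted`, `significant`.
#' @export
run_enrichment <- function(query_genes, annotation, exclusions = character(),
                           alpha = 0.05) {
  stopifnot(inherits(annotation, "annotation_set"))
  query <- sort(unique(as.character(query_genes)))
  query <- setdiff(query, exclusions)
  unknown <- setdiff(query, annotation$genome_genes)
  if (length(unknown) > 0L) {
    warning("removing query gene(s) absent from genome background: ",
            paste(unknown, collapse = ", "))
    query <- setdiff(query, unknown)
  }
  if (length(query) == 0L) stop("empty query after exclusions", call. = FALSE)
  N <- length(annotation$genome_genes)
  n <- length(query)
  cats <- annotation$categories
  cats <- cats[vapply(cats, length, integer(1)) >= 2L]  # single-gene categories excluded
  if (length(cats) == 0L) stop("no testable categories (all have one gene)", call. = FALSE)
  rows <- lapply(names(cats), function(cat) {
    members <- cats[[cat]]
    hits <- intersect(query, members)
    k <- length(hits)
    K <- length(members)
    data.frame(
      category = cat,
      genes = paste(hits, collapse = ";"),
      k = k, n = n, K = K, N = N,
      score = enrichment_score(k, n, K, N),
      p_raw = hypergeom_pvalue(k, n, K, N)
    )
  })
  res <- do.call(rbind, rows)
  res$p_adjusted <- bh_adjust(res$p_raw)
  res$significant <- res$p_adjusted < alpha
  res <- res[order(res$p_raw, res$category), , drop = FALSE]
  rownames(res) <- NULL
  res
}
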
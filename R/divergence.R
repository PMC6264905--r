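#' Collapse replicate fitness measurements to a strain x condition matrix
#'
#' @param fitness Long-format data frame with columns `strain`, `condition`,
#'   `rate` (and optionally `replicate`). Replicates are averaged.
#' @return Numeric matrix, strains in rows, conditions in columns.
#' @export
fitness_matrix <- function(fitness) {
  need <- c("strain", "condition", "rate")
  if (!all(need %in% names(fitness))) {
    stop("fitness table needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  agg <- stats::aggregate(rate ~ strain + condition, data = fitness, FUN = mean)
  strains <- unique(fitness$strain)
  conditions <- unique(fitness$condition)
  m <- matrix(NA_real_, nrow = length(strains), ncol = length(conditions),
              dimnames = list(strains, conditions))
  m[cbind(match(agg$strain, strains), match(agg$condition, conditions))] <- agg$rate
  if (anyNA(m)) {
    stop("every (strain, condition) cell needs at least one replicate", call. = FALSE)
  }
  m
}

#' Normalize a fitness matrix by per-condition means
#'
#' Divides each fitness value by the mean of all fitness values measured in
#' the same condition, bringing all conditions onto a comparable scale for
#' clustering. After normalization every column mean is 1.
#'
#' @param matrix Numeric strain x condition matrix.
#' @return Matrix of the same shape with unit column means.
#' @export
normalize_by_condition_mean <- function(matrix) {
  matrix <- as.matrix(matrix)
  mu <- colMeans(matrix)
  bad <- !is.finite(mu) | mu == 0
  if (any(bad)) {
    nm <- colnames(matrix)
    if (is.null(nm)) nm <- as.character(which(bad))
    stop("zero or non-finite column mean for condition(s): ",
         paste(nm[bad], collapse = ", "), call. = FALSE)
  }
  sweep(matrix, 2, mu, "/")
}

#' Hierarchical clustering of strains or conditions
#'
#' Agglomerative clustering (default: Euclidean distance, complete linkage)
#' of either the strain rows or the condition columns of a (normalized)
#' fitness matrix.
#'
#' @param matrix Numeric strain x condition matrix (typically the output of
#'   [normalize_by_condition_mean()]).
#' @param axis `"strains"` (rows) or `"conditions"` (columns).
#' @param dist_method Distance measure passed to [stats::dist()].
#' @param linkage Agglomeration method passed to [stats::hclust()].
#' @return An [stats::hclust] merge tree.
#' @export
hierarchical_cluster <- function(matrix, axis = c("strains", "conditions"),
                                 dist_method = "euclidean", linkage = "complete") {
  axis <- match.arg(axis)
  matrix <- as.matrix(matrix)
  if (anyNA(matrix) || any(!is.finite(matrix))) {
    stop("matrix contains missing or non-finite values", call. = FALSE)
  }
  x <- if (axis == "strains") matrix else t(matrix)
  if (nrow(x) < 2L) stop("need at least 2 items on the chosen axis", call. = FALSE)
  stats::hclust(stats::dist(x, method = dist_method), method = linkage)
}

#' PCA of a fitness matrix with explained-variance fractions
#'
#' Principal component analysis of raw fitness values (no per-condition
#' normalization): columns are centered but not scaled, as the standard
#' `prcomp` default.
#'
#' @param matrix Numeric strain x condition matrix with >= 2 rows and
#'   >= 2 columns.
#' @return List with `scores` (strain coordinates), `loadings` (orthonormal
#'   component directions) and `explained_fraction` (variance fractions
#'   summing to 1).
#' @export
pca_explained_variance <- function(matrix) {
  matrix <- as.matrix(matrix)
  if (nrow(matrix) < 2L || ncol(matrix) < 2L) {
    stop("need at least 2 strains and 2 conditions", call. = FALSE)
  }
  if (any(!is.finite(matrix))) stop("matrix contains non-finite values", call. = FALSE)
  fit <- stats::prcomp(matrix, center = TRUE, scale. = FALSE)
  v <- fit$sdev^2
  if (sum(v) == 0) stop("matrix has rank 0 after centering", call. = FALSE)
  list(scores = fit$x, loadings = fit$rotation,
       explained_fraction = v / sum(v))
}

#' Pearson correlation-distance matrix between conditions
#'
#' d_ij = 1 - r(column_i, column_j), where r is the Pearson correlation of
#' the two conditions' fitness values across strains. A small distance means
#' clones rank similarly in the two conditions; d lies in \[0, 2\].
#'
#' @param matrix Numeric strain x condition matrix (>= 3 strains; each
#'   condition column must have nonzero variance).
#' @return Symmetric condition x condition distance matrix with zero
#'   diagonal, of class `condition_distance`.
#' @export
condition_distance_matrix <- function(matrix) {
  matrix <- as.matrix(matrix)
  if (nrow(matrix) < 3L) stop("need at least 3 strains", call. = FALSE)
  sds <- apply(matrix, 2, stats::sd)
  if (any(sds == 0 | !is.finite(sds))) {
    nm <- colnames(matrix)
    if (is.null(nm)) nm <- as.character(seq_len(ncol(matrix)))
    stop("zero-variance fitness column for condition(s): ",
         paste(nm[sds == 0 | !is.finite(sds)], collapse = ", "), call. = FALSE)
  }
  d <- 1 - stats::cor(matrix)
  diag(d) <- 0
  structure(d, class = c("condition_distance", "matrix"))
}

upper_tri_values <- function(d) d[upper.tri(d)]

#' One-tailed divergence test on pooled condition distances
#'
#' Pools the upper-triangle Pearson correlation distances of each group's
#' condition distance matrix (C(m, 2) values per group for m conditions) and
#' applies a one-tailed Wilcoxon rank-sum test of whether group 1's
#' distances are greater than group 2's, i.e. whether group 1's clones
#' diverged more across conditions.
#'
#' @param d_group1,d_group2 Condition distance matrices from
#'   [condition_distance_matrix()] over the same condition set.
#' @return List with `W`, one-tailed `p`, and the pooled distance vectors.
#' @export
divergence_test <- function(d_group1, d_group2) {
  d_group1 <- as.matrix(d_group1)
  d_group2 <- as.matrix(d_group2)
  if (!identical(dim(d_group1), dim(d_group2)) ||
      !identical(colnames(d_group1), colnames(d_group2))) {
    stop("the two groups must share the same condition set", call. = FALSE)
  }
  x <- upper_tri_values(d_group1)
  y <- upper_tri_values(d_group2)
  # exact enumeration for small samples, normal approximation with tie and
  # continuity correction otherwise
  exact <- min(length(x), length(y)) < 20
  fit <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "greater", exact = exact,
                       correct = TRUE)
  )
  list(W = unname(fit$statistic), p = unname(fit$p.value),
       distances_group1 = x, distances_group2 = y)
}

#' One-tailed test on per-condition variances of fitness improvements
#'
#' For each condition, computes the variance of clone fitness improvements
#' within each group, then tests across the paired condition variances
#' whether group 1's variances exceed group 2's (one-tailed paired t test).
#' Conditions with fewer than 2 clones in either group are excluded with a
#' warning.
#'
#' @param improvements_group1,improvements_group2 Clone x condition numeric
#'   matrices of fitness improvements, sharing the same condition columns.
#' @return List with per-condition `variances` (data frame), `t`, `df` and
#'   one-tailed `p`.
#' @export
improvement_variance_test <- function(improvements_group1, improvements_group2) {
  g1 <- as.matrix(improvements_group1)
  g2 <- as.matrix(improvements_group2)
  if (ncol(g1) != ncol(g2) || !identical(colnames(g1), colnames(g2))) {
    stop("the two groups must share the same condition set", call. = FALSE)
  }
  if (ncol(g1) < 2L) stop("need at least 2 conditions", call. = FALSE)
  usable <- colSums(!is.na(g1)) >= 2 & colSums(!is.na(g2)) >= 2
  if (any(!usable)) {
    warning("excluding condition(s) with < 2 clones: ",
            paste(colnames(g1)[!usable], collapse = ", "))
  }
  v1 <- apply(g1[, usable, drop = FALSE], 2, stats::var, na.rm = TRUE)
  v2 <- apply(g2[, usable, drop = FALSE], 2, stats::var, na.rm = TRUE)
  if (all(v1 == v2)) {
    # identical per-condition variances: no evidence either way
    res <- list(t = 0, df = sum(usable) - 1, p = 0.5)
  } else {
    res <- paired_t_one_tailed(v1, v2, alternative = "greater")
  }
  variances <- data.frame(condition = colnames(g1)[usable],
                          var_group1 = unname(v1), var_group2 = unname(v2))
  list(variances = variances, t = res$t, df = res$df, p = res$p)
}
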
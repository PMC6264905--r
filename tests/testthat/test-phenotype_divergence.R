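make_matrix <- function(nr = 6, nc = 4, seed = 13) {
  set.seed(seed)
  m <- matrix(rnorm(nr * nc, 0.35, 0.05), nr, nc,
              dimnames = list(sprintf("s%d", 1:nr), sprintf("c%d", 1:nc)))
  m
}

test_that("per-condition mean normalization gives unit column means and is idempotent", {
  m <- cbind(a = c(2, 2, 2), b = c(1, 2, 3))
  n <- normalize_by_condition_mean(m)
  expect_equal(unname(n[, "a"]), c(1, 1, 1))
  expect_equal(unname(n[, "b"]), c(0.5, 1, 1.5))
  expect_equal(colMeans(n), c(a = 1, b = 1), tolerance = 1e-12)
  expect_equal(normalize_by_condition_mean(n), n, tolerance = 1e-12)
  expect_error(normalize_by_condition_mean(cbind(ok = 1:3, zero = c(-1, 0, 1))),
               "zero")
})

test_that("hierarchical clustering matches a brute-force agglomeration oracle", {
  m <- make_matrix(6, 4)
  got <- hierarchical_cluster(m, axis = "strains")

  # naive O(n^3) complete-linkage agglomeration over the Euclidean distances
  d <- as.matrix(stats::dist(m))
  active <- as.list(seq_len(nrow(m)))
  heights <- numeric(0)
  while (length(active) > 1L) {
    best <- c(NA, NA); best_h <- Inf
    for (i in seq_along(active)) {
      for (j in seq_along(active)) {
        if (i >= j) next
        h <- max(d[active[[i]], active[[j]]])  # complete linkage
        if (h < best_h) { best_h <- h; best <- c(i, j) }
      }
    }
    heights <- c(heights, best_h)
    active[[best[1]]] <- c(active[[best[1]]], active[[best[2]]])
    active[[best[2]]] <- NULL
  }
  expect_equal(got$height, heights, tolerance = 1e-12)

  # identical rows merge at height zero, first
  m2 <- rbind(m, m[1, , drop = FALSE])
  expect_equal(min(hierarchical_cluster(m2, "strains")$height), 0)

  # three points on a line: closest pair merges first
  line <- cbind(x = c(0, 1, 10))
  rownames(line) <- c("p0", "p1", "p10")
  hc <- hierarchical_cluster(cbind(line, line), "strains")
  expect_equal(sort(hc$merge[1, ]), c(-2, -1))
  expect_error(hierarchical_cluster(rbind(m[1, ]), "strains"), "at least 2")
})

test_that("PCA explained fractions match the covariance eigenvalue oracle", {
  m <- make_matrix(5, 3, seed = 21)
  got <- pca_explained_variance(m)
  ev <- eigen(stats::cov(m), symmetric = TRUE)$values
  expect_equal(sum(got$explained_fraction), 1, tolerance = 1e-12)
  expect_equal(got$explained_fraction, ev / sum(ev), tolerance = 1e-10)
  expect_equal(crossprod(got$loadings), diag(ncol(m)), tolerance = 1e-10,
               ignore_attr = TRUE)

  # rank-1 matrix: PC1 explains everything
  v <- c(1, 2, 3)
  r1 <- outer(c(1, 2, 4, 8), v) + 5
  expect_equal(pca_explained_variance(r1)$explained_fraction[1], 1,
               tolerance = 1e-12)

  # permutation-invariant to row order
  perm <- sample(nrow(m))
  expect_equal(pca_explained_variance(m[perm, ])$explained_fraction,
               got$explained_fraction, tolerance = 1e-12)
  expect_error(pca_explained_variance(matrix(1, 3, 3)), "rank 0")
})

test_that("condition distances are 1 - Pearson r with the documented geometry", {
  m <- make_matrix(8, 3, seed = 3)
  dup <- cbind(m, dupli = m[, 1])
  d <- condition_distance_matrix(dup)
  expect_equal(d["c1", "dupli"], 0, tolerance = 1e-12)
  expect_true(all(d >= 0 & d <= 2))
  expect_equal(as.matrix(d), t(as.matrix(d)))
  expect_equal(diag(as.matrix(d)), rep(0, 4), ignore_attr = TRUE)

  x <- c(-2, -1, 0, 1, 2)
  anti <- cbind(a = x, b = -x, c = c(1, -2, 0, 2, -1))
  d2 <- condition_distance_matrix(anti)
  expect_equal(d2["a", "b"], 2)                      # perfect anticorrelation
  expect_equal(d2["a", "c"], 1, tolerance = 1e-12)   # orthogonal after centering

  # invariant under positive affine rescaling of any column
  resc <- sweep(m, 2, c(2, 5, 0.1), "*") + 3
  expect_equal(as.matrix(condition_distance_matrix(resc)),
               as.matrix(condition_distance_matrix(m)), tolerance = 1e-12)
  expect_error(condition_distance_matrix(cbind(m, flat = rep(1, 8))),
               "zero-variance")
})

test_that("divergence test is one-tailed on pooled upper-triangle distances", {
  m1 <- make_matrix(9, 6, seed = 41)
  d1 <- condition_distance_matrix(m1)
  same <- divergence_test(d1, d1)
  expect_equal(same$p, 0.5, tolerance = 0.02)
  expect_equal(length(same$distances_group1), choose(6, 2))

  # complete separation: group 1 distances all strictly greater
  d_hi <- as.matrix(d1); d_hi[upper.tri(d_hi)] <- d_hi[upper.tri(d_hi)] + 10
  d_hi[lower.tri(d_hi)] <- t(d_hi)[lower.tri(d_hi)]
  class(d_hi) <- class(d1)
  sep <- divergence_test(d_hi, d1)
  expect_lt(sep$p, 1e-5)
  expect_error(divergence_test(d1, condition_distance_matrix(m1[, 1:4])),
               "same condition set")
})

test_that("variance test compares per-condition improvement variances one-tailed", {
  set.seed(55)
  g2 <- matrix(rnorm(9 * 11), 9, 11, dimnames = list(NULL, sprintf("c%d", 1:11)))
  same <- improvement_variance_test(g2, g2)
  expect_equal(same$t, 0)
  expect_equal(same$p, 0.5)
  expect_equal(same$df, 10)

  # scaling one group 3x about its column means gives 9x the variance
  g1 <- sweep(g2, 2, colMeans(g2)) * 3
  g1 <- sweep(g1, 2, colMeans(g2), "+")
  res <- improvement_variance_test(g1, g2)
  expect_equal(res$variances$var_group1, 9 * res$variances$var_group2,
               tolerance = 1e-9)
  expect_lt(res$p, 0.01)

  # a condition with a single clone in one group is dropped with a warning
  g1_na <- g1; g1_na[2:9, 1] <- NA
  expect_warning(res2 <- improvement_variance_test(g1_na, g2), "excluding")
  expect_equal(nrow(res2$variances), 10)
})
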
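test_that("high-prevalence filter removes modules above the pooled cutoff", {
  mk_presence <- function(n, carriers_per_module) {
    mat <- sapply(carriers_per_module, function(k)
      c(rep(TRUE, k), rep(FALSE, n - k)))
    colnames(mat) <- sprintf("M%02d", seq_along(carriers_per_module))
    mat
  }
  cfg <- analysis_config()
  # with 29 pooled isolates the cutoff is floor(0.8 * 29) = 23: strictly
  # more than 23 carriers -> removed; exactly 23 -> retained
  pres <- mk_presence(29, c(24, 23, 10))
  expect_equal(high_prevalence_filter(pres, cfg), c("M02", "M03"))
  # n = 10 at fraction 0.8: 9 carriers > 8 -> removed
  pres10 <- mk_presence(10, c(9, 8))
  expect_equal(high_prevalence_filter(pres10, cfg), "M02")
})

test_that("chi-squared test matches the Pearson formula and its properties", {
  tab <- matrix(c(10, 30, 20, 40), 2)
  res <- chisq_test(tab)
  oracle <- oracle_chisq(tab)
  expect_equal(res$statistic, oracle$statistic, tolerance = 1e-10)
  expect_equal(res$statistic, 100 / 126, tolerance = 1e-10)  # ~0.794
  expect_equal(res$df, 1)

  # proportional rows -> statistic 0, p = 1
  prop <- matrix(c(10, 20, 30, 60), 2)
  expect_equal(chisq_test(prop)$statistic, 0, tolerance = 1e-12)
  expect_equal(chisq_test(prop)$p, 1)

  # doubling all counts doubles the statistic
  expect_equal(chisq_test(2 * tab)$statistic, 2 * res$statistic,
               tolerance = 1e-10)

  # permutation invariance + random-table oracle sweep
  set.seed(7)
  for (i in 1:200) {
    r <- sample(2:4, 1); c <- sample(2:4, 1)
    m <- matrix(sample(1:30, r * c, replace = TRUE), r)
    expect_equal(chisq_test(m)$statistic, oracle_chisq(m)$statistic,
                 tolerance = 1e-9)
    perm <- m[sample(r), sample(c), drop = FALSE]
    expect_equal(chisq_test(perm)$statistic, chisq_test(m)$statistic,
                 tolerance = 1e-9)
  }

  expect_error(chisq_test(matrix(c(1, 2), 1)), ">= 2 rows")
  expect_warning(chisq_test(matrix(c(5, 1, 6, 2, 0, 0), 2)), "all-zero")
})

test_that("pairwise chi-squared covers every consortium pair with BH control", {
  counts <- matrix(c(40, 40, 10, 10, 25, 40, 25, 10, 35), 3, byrow = TRUE,
                   dimnames = list(c("A", "B", "C"), c("s1", "s2", "s3")))
  res <- pairwise_chisq(counts)
  expect_equal(nrow(res), 3)
  expect_equal(res$q, stats::p.adjust(res$p, "BH"))
})

test_that("dissimilarity indices are medians of all pairwise Euclidean distances", {
  same <- matrix(1, 3, 4)
  d <- dissimilarity_index(same, name = "same")
  expect_equal(d$pairwise_distances, rep(0, 3))
  expect_equal(d$median, 0)

  two <- rbind(c(1, 2, 3), c(1, 2, 4))
  expect_equal(dissimilarity_index(two)$median, 1)

  three <- matrix(rnorm(12), 3)
  expect_length(dissimilarity_index(three)$pairwise_distances, 3)
  expect_error(dissimilarity_index(matrix(1, 1, 3)), "< 2 members")
})

test_that("Kruskal-Wallis and Dunn match rank-based oracles", {
  groups <- list(a = c(1, 2, 3), b = c(11, 12, 13), c = c(21, 22, 23))
  res <- kruskal_dunn(groups)
  expect_equal(res$statistic, oracle_kw(groups), tolerance = 1e-10)
  expect_equal(res$pairwise$z[1], oracle_dunn_z(groups, 1, 2),
               tolerance = 1e-10)

  # permuting group order leaves the statistic unchanged
  res_perm <- kruskal_dunn(groups[c(3, 1, 2)])
  expect_equal(res_perm$statistic, res$statistic, tolerance = 1e-12)

  # identical groups -> large p through the degenerate path
  flat <- list(a = c(5, 5), b = c(5, 5), c = c(5, 5))
  expect_gte(kruskal_dunn(flat)$p, 0.9)

  # random all-distinct and tied data up to n = 8 per group
  set.seed(13)
  for (i in 1:50) {
    g <- lapply(1:3, function(j) sample(1:100, sample(2:8, 1)))
    names(g) <- c("x", "y", "z")
    res <- kruskal_dunn(g)
    expect_equal(res$statistic, oracle_kw(g), tolerance = 1e-9)
    for (pr in 1:3) {
      ij <- utils::combn(1:3, 2)[, pr]
      expect_equal(res$pairwise$z[pr], oracle_dunn_z(g, ij[1], ij[2]),
                   tolerance = 1e-9)
    }
    g_tied <- lapply(g, function(v) round(v / 10))
    if (all(lengths(lapply(g_tied, unique)) >= 1) &&
        length(unique(unlist(g_tied))) > 1) {
      expect_equal(kruskal_dunn(g_tied)$statistic, oracle_kw(g_tied),
                   tolerance = 1e-9)
    }
  }
})

test_that("PCA scores agree with a direct eigendecomposition", {
  set.seed(5)
  mat <- matrix(rnorm(8 * 5), 8, 5)
  res <- pca_scores(mat)
  oracle <- oracle_pca_scores(mat)
  for (j in 1:5) {
    expect_equal(abs(res$scores[, j]), abs(oracle[, j]), tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
  # centroid of scores is the origin; explained fractions sum to 1
  expect_equal(unname(colMeans(res$scores)), rep(0, 5), tolerance = 1e-10)
  expect_equal(sum(res$explained), 1, tolerance = 1e-12)

  # rank-1 matrix: PC1 carries all variance
  r1 <- outer(1:6, c(2, 1, 3))
  expect_equal(pca_scores(r1)$explained[1], 1, tolerance = 1e-12)

  # identical rows: degenerate, all-zero scores
  flat <- matrix(3, 4, 3)
  res_flat <- pca_scores(flat)
  expect_true(res_flat$degenerate)
  expect_true(all(res_flat$scores == 0))

  # row reordering permutes scores but preserves them (up to sign)
  perm <- sample(nrow(mat))
  res_perm <- pca_scores(mat[perm, ])
  expect_equal(abs(res_perm$scores[order(perm), 1]), abs(res$scores[, 1]),
               tolerance = 1e-8, ignore_attr = TRUE)

  # grouped call returns one ellipse per group
  res_g <- pca_scores(mat, groups = rep(c("a", "b"), each = 4))
  expect_named(res_g$ellipses, c("a", "b"))
  expect_equal(res_g$ellipses$a$radius, sqrt(qchisq(0.95, 2)))
})

test_that("subcategory contingency counts distinct KOs per consortium", {
  h <- functional_hierarchy(data.frame(
    ko = c("K00001", "K00002", "K00003"),
    pathway = c("p1", "p2", "p3"),
    category = "cat",
    subcategory = c("s1", "s1", "s2")))
  consA <- consortium_spec("A", list(
    genome_annotation("a1", c(K00001 = 2L, K00003 = 1L))))
  consB <- consortium_spec("B", list(
    genome_annotation("b1", c(K00001 = 1L, K00002 = 1L))))
  mat <- subcategory_counts(list(A = consA, B = consB), h)
  expect_equal(mat["A", "s1"], 1L)
  expect_equal(mat["B", "s1"], 2L)
  # with multiplicity, copy numbers count
  mat_m <- subcategory_counts(list(A = consA, B = consB), h,
                              multiplicity = TRUE)
  expect_equal(mat_m["A", "s1"], 2L)
})
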
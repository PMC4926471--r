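test_that("chain parsing enforces stage grammar", {
  ch <- classifier_chain("auc+pca+lda")
  expect_equal(ch$stages, c("auc_select", "pca", "lda"))
  expect_s3_class(classifier_chain("svm"), "classifier_chain")
  expect_error(classifier_chain("auc+pca"), "terminal")
  expect_error(classifier_chain("lda+svm"), "terminal")
  expect_error(classifier_chain("pca+lda+auc"), "terminal")
  expect_error(classifier_chain("foo+lda"), "unknown")
})

make_blobs <- function(n_per, centers, sdev = 1, n_feat = 3, seed = 1) {
  set.seed(seed)
  x <- do.call(rbind, lapply(seq_along(centers), function(g) {
    matrix(rnorm(n_per * n_feat, centers[g], sdev), n_per, n_feat)
  }))
  dimnames(x) <- list(paste0("s", seq_len(nrow(x))), paste0("r", seq_len(n_feat)))
  list(x = x, labels = factor(rep(LETTERS[seq_along(centers)], each = n_per)))
}

test_that("chains fit separable data and reject degenerate inputs", {
  b <- make_blobs(20, c(0, 10), sdev = 1) # 10 pooled-SD separation
  for (spec in c("lda", "svm", "pca+lda", "auc+svm")) {
    fit <- fit_chain(classifier_chain(spec, auc_min = 0.6), b$x, b$labels)
    expect_equal(mean(predict(fit, b$x) == b$labels), 1,
                 info = spec)
  }
  expect_error(fit_chain(classifier_chain("lda"), b$x, rep("A", 40)),
               "2 classes")
})

test_that("pca stage rescues LDA on rank-deficient matrices", {
  set.seed(31)
  x <- matrix(rnorm(5 * 100), 5, 100,
              dimnames = list(paste0("s", 1:5), paste0("r", 1:100)))
  lab <- factor(c("A", "A", "A", "B", "B"))
  fit <- fit_chain(classifier_chain("pca+lda", pca_var = 0.8), x, lab)
  expect_s3_class(fit, "fitted_chain")
  # LDA produces classes - 1 axes on full-rank inputs
  b <- make_blobs(10, c(0, 5, 10), seed = 32)
  fit3 <- fit_chain(classifier_chain("lda"), b$x, b$labels)
  expect_equal(ncol(fit3$ld_coordinates), 2L)
})

test_that("repeated CV is deterministic, leakage-free and validates folds", {
  b <- make_blobs(10, c(0, 6, 12), seed = 33)
  ch <- classifier_chain("pca+lda")
  cv1 <- repeated_cv(ch, b$x, b$labels, n_repeats = 5, n_folds = 5, seed = 7)
  cv2 <- repeated_cv(ch, b$x, b$labels, n_repeats = 5, n_folds = 5, seed = 7)
  expect_identical(cv1, cv2)
  expect_true(cv1$q025 <= cv1$accuracy_mean && cv1$accuracy_mean <= cv1$q975)
  expect_gt(cv1$accuracy_mean, 95) # separable blobs
  expect_error(repeated_cv(ch, b$x, b$labels, n_repeats = 1, n_folds = 31, seed = 1),
               "exceeds")
  # shuffled labels: accuracy falls to chance (light version of the
  # no-leakage null; the full check is an acceptance criterion)
  set.seed(34)
  null_lab <- sample(rep(c("A", "B"), 15))
  cv0 <- repeated_cv(classifier_chain("auc+lda", auc_min = 0.6),
                     b$x, null_lab, n_repeats = 30, n_folds = 5, seed = 8)
  expect_lt(abs(cv0$accuracy_mean - 50), 12)
})

test_that("cv_table mirrors the benchmark column layout", {
  b <- make_blobs(8, c(0, 8), seed = 35)
  cv <- repeated_cv(classifier_chain("lda"), b$x, b$labels,
                    n_repeats = 3, n_folds = 4, seed = 2)
  tab <- cv_table(list("LDA" = cv))
  expect_equal(names(tab),
               c("Classifier", "Accuracy Mean", "2.5% Quantile", "97.5% Quantile"))
})

test_that("the SVM separates blobs with both kernels", {
  b <- make_blobs(15, c(0, 4, 8), sdev = 0.8, seed = 36)
  for (kern in c("rbf", "linear")) {
    m <- svm_fit(b$x, b$labels, kernel = kern)
    expect_gte(mean(predict(m, b$x) == b$labels), 0.95)
  }
})

test_that("UPGMA reproduces the worked 3-leaf example", {
  d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  den <- upgma(d)
  expect_equal(den$heights, c(1, 2))
  expect_equal(to_newick(den), "((A:1,B:1):1,C:2);")
  # 2 leaves merge at half the distance
  d2 <- matrix(c(0, 6, 6, 0), 2, 2, dimnames = list(c("x", "y"), c("x", "y")))
  expect_equal(upgma(d2)$heights, 3)
  expect_error(upgma(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("UPGMA matches the naive agglomerator on random matrices", {
  set.seed(37)
  for (k in 1:10) {
    d <- random_dist_matrix(8)
    den <- upgma(d)
    coph <- as.matrix(stats::cophenetic(den$hclust)) / 2
    expect_equal(unname(coph[rownames(d), rownames(d)]),
                 unname(oracle_upgma_cophenetic(d)), tolerance = 1e-10)
    # ultrametric: merge heights non-decreasing
    expect_true(!is.unsorted(den$heights))
  }
})

test_that("Mantel test detects affine relationships and is seed-stable", {
  set.seed(38)
  d1 <- random_dist_matrix(10)
  mt <- mantel_test(d1, 2 * d1, n_perm = 99, seed = 5)
  expect_equal(mt$r, 1)
  expect_equal(mt$p_value, 0.01)
  mt2 <- mantel_test(d1, 2 * d1, n_perm = 99, seed = 5)
  expect_identical(mt, mt2)
  expect_error(mantel_test(d1, random_dist_matrix(4), seed = 1), "size")
  # independent matrices: weak correlation, non-significant
  set.seed(39)
  d3 <- random_dist_matrix(12)
  d4 <- random_dist_matrix(12)
  mt3 <- mantel_test(d3, d4, n_perm = 299, seed = 6)
  expect_lt(abs(mt3$r), 0.4)
  expect_gt(mt3$p_value, 0.05)
})

test_that("Mantel statistic agrees with the vegan oracle", {
  skip_if_not_installed("vegan")
  set.seed(40)
  d1 <- random_dist_matrix(9)
  d2 <- random_dist_matrix(9)
  for (meth in c("pearson", "spearman")) {
    mine <- mantel_test(d1, d2, n_perm = 49, method = meth, seed = 1)
    ref <- vegan::mantel(as.dist(d1), as.dist(d2), method = meth,
                         permutations = 49)
    expect_equal(mine$r, unname(ref$statistic), tolerance = 1e-12)
  }
})

test_that("Mantel null p-values are roughly uniform", {
  set.seed(41)
  ps <- vapply(1:60, function(i) {
    mantel_test(random_dist_matrix(7), random_dist_matrix(7),
                n_perm = 49, seed = 100 + i)$p_value
  }, 0)
  expect_gt(mean(ps), 0.35)
  expect_lt(mean(ps), 0.65)
})

test_that("LD distance matrices are Euclidean and match brute force", {
  expect_true(all(ld_distance_matrix(matrix(1, 4, 2)) == 0))
  expect_equal(ld_distance_matrix(rbind(c(0, 0), c(3, 4)))[1, 2], 5)
  set.seed(42)
  m <- matrix(rnorm(18), 6, 3, dimnames = list(paste0("s", 1:6), NULL))
  d <- ld_distance_matrix(m)
  for (i in 1:6) for (j in 1:6) {
    expect_equal(d[i, j], sqrt(sum((m[i, ] - m[j, ])^2)))
  }
  expect_error(ld_distance_matrix(matrix(c(1, NA), 1, 2)), "finite")
})
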
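test_that("multi-class AUC reproduces hand-derived values", {
  expect_equal(hand_till_auc(c(1, 2, 10, 11), c("A", "A", "B", "B")), 1)
  expect_equal(hand_till_auc(rep(3, 6), rep(c("A", "B"), 3)), 0.5)
  expect_equal(hand_till_auc(c(1, 3, 2, 4), c("A", "A", "B", "B")), 0.75)
  expect_error(hand_till_auc(1:4, rep("A", 4)), "2 classes")
  expect_error(hand_till_auc(1:3, factor(c("A", "B", "A"), levels = c("A", "B", "C"))),
               NA) # empty levels are dropped, not an error
})

test_that("AUC equals the brute-force pair-counting oracle", {
  set.seed(21)
  for (k in 1:50) {
    n_cls <- sample(2:4, 1)
    labels <- factor(sample(letters[1:n_cls], 12, replace = TRUE))
    while (length(unique(labels)) < n_cls) {
      labels <- factor(sample(letters[1:n_cls], 12, replace = TRUE))
    }
    values <- sample(1:6, 12, replace = TRUE) # ties likely
    expect_equal(hand_till_auc(values, labels),
                 oracle_hand_till(values, labels))
  }
})

test_that("AUC is invariant to strictly monotone transforms", {
  set.seed(22)
  v <- rnorm(30)
  lab <- sample(c("x", "y", "z"), 30, replace = TRUE)
  m <- hand_till_auc(v, lab)
  expect_equal(hand_till_auc(exp(v), lab), m)
  expect_equal(hand_till_auc(rank(v), lab), m)
})

test_that("MDL discretization accepts informative splits and rejects noise", {
  expect_equal(mdl_discretize(c(1, 2, 3, 4), c("A", "A", "B", "B")), 2.5)
  expect_length(mdl_discretize(rep(2, 6), rep(c("A", "B"), 3)), 0)
  # shuffled labels at n = 8: usually no cut survives MDL
  set.seed(23)
  rejections <- sum(vapply(1:100, function(i) {
    length(mdl_discretize(1:8, sample(rep(c("A", "B"), 4)))) == 0
  }, TRUE))
  expect_gte(rejections, 85)
})

test_that("Chi-squared scoring matches closed forms", {
  # [[10, 0], [0, 10]] table -> chi2 = 20
  expect_equal(chi_squared_score(rep(c(1, 2), each = 10),
                                 rep(c("A", "B"), each = 10)), 20)
  # uninformative attribute scores 0 via MDL rejection
  set.seed(24)
  expect_equal(chi_squared_score(1:8, sample(rep(c("A", "B"), 4))), 0)
  # 3-class perfectly separable 12-sample toy: N * (k - 1) = 24
  expect_equal(chi_squared_score(1:12, rep(c("A", "B", "C"), each = 4)), 24)
  # invariance to order-reversal (bin relabeling)
  v <- c(1, 1, 2, 2, 5, 5, 6, 6, 9, 9, 10, 10)
  lab <- rep(c("A", "B", "C"), each = 4)
  expect_equal(chi_squared_score(-v, lab), chi_squared_score(v, lab))
})

test_that("PCA retains the smallest prefix reaching the variance threshold", {
  # rank-1 matrix: one component carries all variance
  x <- outer(1:6, c(1, 2, 3, 4))
  dimnames(x) <- list(paste0("s", 1:6), paste0("r", 1:4))
  pm <- pca_extract(x, 0.8)
  expect_equal(pm$n_retained, 1L)
  expect_equal(sum(pm$var_frac[1]), 1, tolerance = 1e-12)
  # full reconstruction reproduces the centered matrix
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  recon <- pc$x %*% t(pc$rotation)
  expect_equal(recon, sweep(x, 2, colMeans(x)), tolerance = 1e-10,
               ignore_attr = TRUE)
  # isotropic noise in 10 dims: ~equal eigenvalues, k = ceiling(0.8 * 10)
  set.seed(25)
  z <- matrix(rnorm(500 * 10), 500, 10,
              dimnames = list(NULL, paste0("d", 1:10)))
  expect_equal(pca_extract(z, 0.8)$n_retained, 8L)
  expect_error(pca_extract(x, 1.2), "variance_threshold")
  expect_error(pca_extract(x[1, , drop = FALSE]), "2 samples")
})

test_that("PCA scores are sample-order invariant up to sign", {
  set.seed(26)
  x <- matrix(rnorm(40), 8, 5, dimnames = list(paste0("s", 1:8), paste0("r", 1:5)))
  pm1 <- pca_extract(x, 0.99)
  perm <- sample(8)
  pm2 <- pca_extract(x[perm, ], 0.99)
  for (k in seq_len(min(pm1$n_retained, pm2$n_retained))) {
    a <- pm1$scores[perm, k]; b <- pm2$scores[, k]
    expect_true(isTRUE(all.equal(a, b, tolerance = 1e-8, check.attributes = FALSE)) ||
                  isTRUE(all.equal(a, -b, tolerance = 1e-8, check.attributes = FALSE)))
  }
})

test_that("PC-correlation selection ranks aligned regions first", {
  set.seed(27)
  n <- 100
  base <- matrix(rnorm(n * 20), n, 20)
  colnames(base) <- paste0("r", 1:20)
  rownames(base) <- paste0("s", 1:n)
  pm <- pca_extract(region_matrix(base, "IR"), 0.999)
  # plant a region equal to the PC1 scores
  planted <- base
  planted[, 1] <- pm$scores[, 1]
  rm <- region_matrix(planted, "IR")
  sel <- select_by_pc_correlation(rm, n_components = 1, top_k = 5)
  expect_length(sel, 5)
  expect_true("r1" %in% sel)
  expect_gt(unname(attr(sel, "score")[sel == "r1"]), 0.9)
  # against the pre-fitted PCA the planted correlation is exactly 1
  sel_pm <- select_by_pc_correlation(rm, 1, top_k = 1, pca = pm)
  expect_equal(unname(attr(sel_pm, "score")), 1, tolerance = 1e-8)
  # pure-noise region correlates weakly with the PCs of other regions
  noise_scores <- attr(select_by_pc_correlation(rm, 1, top_k = 20), "score")
  expect_lt(median(noise_scores[-1]), 0.3)
  expect_error(select_by_pc_correlation(rm, 1), "exactly one")
})

test_that("discriminatory power ratio handles zero and mismatched inputs", {
  a <- c(r1 = 4, r2 = 2, r3 = 0)
  b <- c(r1 = 4, r2 = 1, r3 = 5)
  expect_equal(discriminatory_power_ratio(b, a)[["r1"]], 1)
  expect_equal(discriminatory_power_ratio(a, b)[["r2"]], 2)
  expect_true(is.na(discriminatory_power_ratio(b, a)[["r3"]]))
  expect_error(discriminatory_power_ratio(a, b[1:2]), "differ")
})
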
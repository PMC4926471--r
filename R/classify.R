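# Classifier chains, repeated stratified cross-validation, UPGMA dendrograms
# on linear-discriminant coordinates, and the Mantel test.

CHAIN_STAGES <- c("auc_select", "chi2_select", "pca", "lda", "svm")
CHAIN_ALIASES <- c(auc = "auc_select", chi2 = "chi2_select", pca = "pca",
                   lda = "lda", svm = "svm")

#' Define a classifier chain
#'
#' A chain is an ordered pipeline of selection/extraction stages ending in
#' exactly one terminal classifier. Chains are written as config strings,
#' e.g. `"auc+pca+lda"`, `"pca+svm"`, `"svm"` -- the seven variants of the
#' standard benchmark tables are all expressible this way.
#'
#' @param spec chain string; stages separated by "+", drawn from
#'   auc (AUC selection), chi2 (Chi-squared selection), pca, and a terminal
#'   lda or svm.
#' @param auc_min minimum multi-class AUC for a region to survive AUC
#'   selection; default 0.8. Ignored when `auc_top_k` is given.
#' @param auc_top_k alternatively keep the k best regions by AUC.
#' @param chi2_top_k number of regions kept by Chi-squared selection;
#'   default keeps all regions with a positive score.
#' @param pca_var PCA variance threshold; default 0.80.
#' @param svm_kernel,svm_cost,svm_gamma passed to [svm_fit()].
#' @return object of class `classifier_chain`.
#' @export
classifier_chain <- function(spec, auc_min = 0.8, auc_top_k = NULL,
                             chi2_top_k = NULL, pca_var = 0.80,
                             svm_kernel = "rbf", svm_cost = 1,
                             svm_gamma = NULL) {
  toks <- tolower(trimws(strsplit(spec, "+", fixed = TRUE)[[1]]))
  unknown <- setdiff(toks, names(CHAIN_ALIASES))
  if (length(unknown)) stop("unknown chain stage(s): ", paste(unknown, collapse = ", "))
  stages <- unname(CHAIN_ALIASES[toks])
  term <- stages %in% c("lda", "svm")
  if (sum(term) != 1L || !term[length(stages)]) {
    stop("chain must end in exactly one terminal classifier (lda or svm)")
  }
  structure(list(spec = spec, stages = stages, auc_min = auc_min,
                 auc_top_k = auc_top_k, chi2_top_k = chi2_top_k,
                 pca_var = pca_var, svm_kernel = svm_kernel,
                 svm_cost = svm_cost, svm_gamma = svm_gamma),
            class = "classifier_chain")
}

#' @export
print.classifier_chain <- function(x, ...) {
  cat("<classifier_chain> ", paste(x$stages, collapse = " -> "), "\n", sep = "")
  invisible(x)
}

.fit_lda <- function(x, labels) {
  tryCatch(
    MASS::lda(x, grouping = labels),
    error = function(e) {
      stop("LDA failed (singular within-class scatter?): ", conditionMessage(e),
           "; consider adding a pca stage before the classifier", call. = FALSE)
    }
  )
}

#' Fit a classifier chain
#'
#' Applies each stage in order to the training matrix: selection stages
#' subset regions, PCA projects to the retained components, and the terminal
#' LDA or SVM is fitted on what remains. When LDA is the terminal stage the
#' fitted object carries the samples' linear-discriminant (LD) coordinates
#' (at most classes - 1 axes), the input to dendrogram construction.
#'
#' @param chain a [classifier_chain()].
#' @param matrix a [region_matrix()] (or plain matrix) of training samples.
#' @param labels class labels aligned with the rows.
#' @return object of class `fitted_chain`; for LDA chains, component
#'   `ld_coordinates` holds the training-sample LD coordinates.
#' @export
fit_chain <- function(chain, matrix, labels) {
  stopifnot(inherits(chain, "classifier_chain"))
  x <- if (inherits(matrix, "region_matrix")) matrix$values else as.matrix(matrix)
  labels <- droplevels(factor(labels))
  if (length(levels(labels)) < 2L) stop("need at least 2 classes")
  if (nrow(x) != length(labels)) stop("labels must align with matrix rows")
  steps <- list()
  for (st in chain$stages) {
    if (st == "auc_select") {
      sc <- apply(x, 2L, hand_till_auc, labels = labels)
      keep <- if (!is.null(chain$auc_top_k)) {
        names(sort(sc, decreasing = TRUE))[seq_len(min(chain$auc_top_k, length(sc)))]
      } else {
        names(sc)[sc >= chain$auc_min]
      }
      if (!length(keep)) keep <- names(which.max(sc)) # never select nothing
      x <- x[, keep, drop = FALSE]
      steps[[length(steps) + 1L]] <- list(type = "select", keep = keep)
    } else if (st == "chi2_select") {
      sc <- apply(x, 2L, chi_squared_score, labels = labels)
      keep <- if (!is.null(chain$chi2_top_k)) {
        names(sort(sc, decreasing = TRUE))[seq_len(min(chain$chi2_top_k, length(sc)))]
      } else {
        names(sc)[sc > 0]
      }
      if (!length(keep)) keep <- names(which.max(sc))
      x <- x[, keep, drop = FALSE]
      steps[[length(steps) + 1L]] <- list(type = "select", keep = keep)
    } else if (st == "pca") {
      pm <- pca_extract(x, chain$pca_var)
      x <- pm$scores
      steps[[length(steps) + 1L]] <- list(type = "pca", model = pm)
    } else if (st == "lda") {
      fit <- .fit_lda(x, labels)
      steps[[length(steps) + 1L]] <- list(type = "lda", model = fit)
    } else { # svm
      fit <- svm_fit(x, labels, kernel = chain$svm_kernel,
                     cost = chain$svm_cost, gamma = chain$svm_gamma)
      steps[[length(steps) + 1L]] <- list(type = "svm", model = fit)
    }
  }
  terminal <- steps[[length(steps)]]
  ld <- NULL
  if (terminal$type == "lda") {
    ld <- predict(terminal$model, x)$x
    rownames(ld) <- rownames(x)
  }
  structure(list(chain = chain, steps = steps, classes = levels(labels),
                 ld_coordinates = ld),
            class = "fitted_chain")
}

#' Predict classes from a fitted chain
#' @param object a `fitted_chain`.
#' @param newdata samples x regions matrix on the training region set.
#' @param ... unused.
#' @return factor of predicted classes.
#' @export
predict.fitted_chain <- function(object, newdata, ...) {
  x <- if (inherits(newdata, "region_matrix")) newdata$values else as.matrix(newdata)
  for (stp in object$steps) {
    x <- switch(stp$type,
      select = x[, stp$keep, drop = FALSE],
      pca = predict(stp$model, x),
      lda = return(factor(as.character(predict(stp$model, x)$class),
                          levels = object$classes)),
      svm = return(factor(as.character(predict(stp$model, x)),
                          levels = object$classes))
    )
  }
  stop("chain had no terminal classifier") # unreachable by construction
}

# Stratified fold assignment: within each class, samples are shuffled and
# dealt round-robin, so fold sizes differ by at most one per class.
.stratified_folds <- function(labels, n_folds) {
  fold <- integer(length(labels))
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

#' Repeated stratified k-fold cross-validation of a chain
#'
#' Every chain stage -- selection, PCA, the classifier -- is refitted inside
#' each training fold; nothing is learned from held-out samples (no
#' leakage). Each repeat's accuracy pools the held-out predictions of its k
#' folds; the distribution over repeats is summarized by its mean and 2.5% /
#' 97.5% quantiles, on the percent scale. Fold assignment is re-randomized
#' per repeat from `seed + repeat`, so results are reproducible and repeats
#' are independently re-runnable.
#'
#' @param chain a [classifier_chain()].
#' @param matrix a [region_matrix()] (or plain matrix).
#' @param labels class labels aligned with rows.
#' @param n_repeats number of repeats; default 1000.
#' @param n_folds folds per repeat; default 10.
#' @param seed base RNG seed (mandatory for reproducibility).
#' @return object of class `cv_result`: list(accuracy_mean, q025, q975,
#'   n_repeats, n_folds, accuracies).
#' @export
repeated_cv <- function(chain, matrix, labels, n_repeats = 1000, n_folds = 10,
                        seed) {
  x <- if (inherits(matrix, "region_matrix")) matrix$values else as.matrix(matrix)
  labels <- droplevels(factor(labels))
  if (n_folds > nrow(x)) stop("n_folds exceeds the number of samples")
  if (missing(seed)) stop("seed is required")
  acc <- numeric(n_repeats)
  for (rep_i in seq_len(n_repeats)) {
    set.seed(seed + rep_i)
    fold <- .stratified_folds(labels, n_folds)
    pred <- factor(rep(NA_character_, nrow(x)), levels = levels(labels))
    for (f in seq_len(n_folds)) {
      test <- fold == f
      if (!any(test)) next
      fit <- fit_chain(chain, x[!test, , drop = FALSE], labels[!test])
      pred[test] <- predict(fit, x[test, , drop = FALSE])
    }
    scored <- !is.na(pred)
    acc[rep_i] <- 100 * mean(pred[scored] == labels[scored])
  }
  structure(list(accuracy_mean = mean(acc),
                 q025 = as.numeric(quantile(acc, 0.025)),
                 q975 = as.numeric(quantile(acc, 0.975)),
                 n_repeats = n_repeats, n_folds = n_folds,
                 accuracies = acc),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> mean %.2f%% [%.2f, %.2f] over %d x %d-fold CV\n",
              x$accuracy_mean, x$q025, x$q975, x$n_repeats, x$n_folds))
  invisible(x)
}

#' Format cross-validation results as a benchmark-style table
#'
#' One row per chain with columns Classifier, Accuracy Mean, 2.5% Quantile,
#' 97.5% Quantile.
#'
#' @param results named list of `cv_result` objects (names = chain specs).
#' @return data.frame.
#' @export
cv_table <- function(results) {
  data.frame(
    Classifier = names(results),
    `Accuracy Mean` = vapply(results, function(r) r$accuracy_mean, 0),
    `2.5% Quantile` = vapply(results, function(r) r$q025, 0),
    `97.5% Quantile` = vapply(results, function(r) r$q975, 0),
    check.names = FALSE, row.names = NULL
  )
}

#' Euclidean distance matrix between samples in LD space
#'
#' @param ld_coordinates samples x axes matrix of linear-discriminant
#'   coordinates (finite).
#' @return symmetric zero-diagonal distance matrix with sample dimnames.
#' @export
ld_distance_matrix <- function(ld_coordinates) {
  m <- as.matrix(ld_coordinates)
  if (any(!is.finite(m))) stop("LD coordinates must be finite")
  as.matrix(dist(m))
}

#' UPGMA hierarchical clustering
#'
#' Average-linkage agglomeration of a distance matrix into an ultrametric
#' tree: two leaves merge at half their average distance, so cophenetic
#' heights are non-decreasing along merges. Export as Newick renders branch
#' lengths as height differences.
#'
#' @param dist_matrix symmetric zero-diagonal distance matrix (or `dist`).
#' @return object of class `upgma_dendrogram` wrapping the merge tree, with
#'   components `hclust`, `phylo` (ape) and `heights` (merge heights, =
#'   distance/2).
#' @export
upgma <- function(dist_matrix) {
  if (!inherits(dist_matrix, "dist")) {
    m <- as.matrix(dist_matrix)
    if (nrow(m) != ncol(m) || any(abs(m - t(m)) > 1e-8)) {
      stop("distance matrix must be symmetric")
    }
    if (any(abs(diag(m)) > 1e-8)) stop("distance matrix must have zero diagonal")
    if (is.null(rownames(m))) {
      rownames(m) <- colnames(m) <- paste0("S", seq_len(nrow(m)))
    }
    dist_matrix <- as.dist(m)
  }
  h <- hclust(dist_matrix, method = "average")
  structure(list(hclust = h, phylo = ape::as.phylo(h),
                 heights = h$height / 2),
            class = "upgma_dendrogram")
}

#' @export
print.upgma_dendrogram <- function(x, ...) {
  cat("<upgma_dendrogram> ", length(x$hclust$labels), " leaves; Newick: ",
      to_newick(x), "\n", sep = "")
  invisible(x)
}

#' Serialize an UPGMA dendrogram as a Newick string
#'
#' Branch lengths are height differences on the ultrametric (distance/2)
#' scale. Within each merge, the earlier-formed cluster is written first,
#' making the string deterministic.
#'
#' @param dendrogram an [upgma()] result.
#' @param digits significant digits for branch lengths.
#' @return Newick string, terminated by ";".
#' @export
to_newick <- function(dendrogram, digits = 10) {
  stopifnot(inherits(dendrogram, "upgma_dendrogram"))
  h <- dendrogram$hclust
  heights <- dendrogram$heights
  fmt <- function(x) format(x, digits = digits, trim = TRUE)
  node <- function(idx, parent_h) {
    if (idx < 0) { # leaf
      paste0(h$labels[-idx], ":", fmt(parent_h))
    } else {
      kids <- h$merge[idx, ]
      kids <- kids[order(-sign(kids), abs(kids))] # clusters before leaves
      paste0("(", paste(vapply(kids, node, "", parent_h = heights[idx]),
                        collapse = ","),
             "):", fmt(parent_h - heights[idx]))
    }
  }
  root <- nrow(h$merge)
  kids <- h$merge[root, ]
  kids <- kids[order(-sign(kids), abs(kids))]
  paste0("(", paste(vapply(kids, node, "", parent_h = heights[root]),
                    collapse = ","), ");")
}

#' Write an UPGMA dendrogram to a Newick file
#' @inheritParams to_newick
#' @param path output path.
#' @export
write_newick <- function(dendrogram, path) {
  writeLines(to_newick(dendrogram), path)
  invisible(path)
}

#' Mantel permutation test between two distance matrices
#'
#' Correlates the upper-triangle entries of two distance matrices over the
#' same leaves and assesses significance by jointly permuting the rows and
#' columns of the second matrix. The permutation p-value uses the
#' add-one estimator \eqn{p = (1 + b) / (1 + m)} where b counts permuted
#' correlations at least as large as the observed one, so p is never 0.
#'
#' @param d1,d2 symmetric distance matrices over the same leaf set; if both
#'   carry dimnames, d2 is aligned to d1's order.
#' @param n_perm number of permutations; default 7000.
#' @param method "pearson" (default) or "spearman".
#' @param seed RNG seed (mandatory).
#' @return object of class `mantel_result`: list(r, p_value, method, n_perm).
#' @export
mantel_test <- function(d1, d2, n_perm = 7000,
                        method = c("pearson", "spearman"), seed) {
  method <- match.arg(method)
  if (missing(seed)) stop("seed is required")
  m1 <- as.matrix(d1); m2 <- as.matrix(d2)
  if (!all(dim(m1) == dim(m2))) stop("distance matrices differ in size")
  if (any(abs(m1 - t(m1)) > 1e-8) || any(abs(m2 - t(m2)) > 1e-8)) {
    stop("distance matrices must be symmetric")
  }
  if (!is.null(rownames(m1)) && !is.null(rownames(m2))) {
    if (!setequal(rownames(m1), rownames(m2))) stop("leaf sets differ")
    m2 <- m2[rownames(m1), rownames(m1)]
  }
  n <- nrow(m1)
  ut <- upper.tri(m1)
  v1 <- m1[ut]
  r_obs <- cor(v1, m2[ut], method = method)
  set.seed(seed)
  b <- 0L
  for (i in seq_len(n_perm)) {
    p <- sample.int(n)
    r_p <- cor(v1, m2[p, p][ut], method = method)
    if (r_p >= r_obs) b <- b + 1L
  }
  structure(list(r = r_obs, p_value = (1 + b) / (1 + n_perm),
                 method = method, n_perm = n_perm),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("<mantel_result> %s r = %.4f, p = %.4g (%d permutations)\n",
              x$method, x$r, x$p_value, x$n_perm))
  invisible(x)
}

#' Write a square distance matrix as TSV
#' @param d distance matrix (or `dist`).
#' @param path output path.
#' @export
write_distance_matrix <- function(d, path) {
  m <- as.matrix(d)
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
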
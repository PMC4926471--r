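# Filter-based feature selection and extraction: multi-class AUC,
# Fayyad-Irani MDL discretization + Chi-squared scoring, PCA at a variance
# threshold, PC-correlation region extraction, and the LCR/IR
# discriminatory-power ratio.

# Orientation-free midrank AUC between two groups of values. With a single
# numeric attribute as the ranking score the two one-vs-one AUCs are
# complementary, so the informative pairwise statistic is max(A, 1 - A).
.pair_auc <- function(x_i, x_j) {
  r <- rank(c(x_i, x_j)) # midranks handle ties
  n_i <- length(x_i); n_j <- length(x_j)
  a <- (sum(r[seq_len(n_i)]) - n_i * (n_i + 1) / 2) / (n_i * n_j)
  max(a, 1 - a)
}

#' Multi-class AUC of one attribute (Hand-Till M)
#'
#' Separability of a single numeric attribute over c classes: the average
#' over all class pairs of the orientation-free one-vs-one rank AUC,
#' \deqn{M = \frac{2}{c(c-1)} \sum_{i<j} \hat A(i,j)}
#' with ties handled by midranks. M = 0.5 for an uninformative (constant or
#' label-independent) attribute and 1 for an attribute that perfectly
#' separates every class pair. Invariant to strictly monotone transforms of
#' the attribute.
#'
#' @param values numeric attribute, one value per sample.
#' @param labels class labels (>= 2 classes, each non-empty).
#' @return M in \[0.5, 1\].
#' @export
hand_till_auc <- function(values, labels) {
  labels <- factor(labels)
  labels <- droplevels(labels)
  cls <- levels(labels)
  if (length(cls) < 2L) stop("need at least 2 classes")
  if (any(tabulate(labels) == 0L)) stop("every class needs at least 1 sample")
  if (length(values) != length(labels)) stop("values/labels length mismatch")
  tot <- 0
  npair <- 0L
  for (i in seq_len(length(cls) - 1L)) {
    for (j in (i + 1L):length(cls)) {
      tot <- tot + .pair_auc(values[labels == cls[i]], values[labels == cls[j]])
      npair <- npair + 1L
    }
  }
  tot / npair
}

#' AUC scores for every region of a matrix
#'
#' @param matrix a [region_matrix()].
#' @param labels class labels aligned with the matrix rows.
#' @return named numeric vector of M per region id.
#' @export
auc_scores <- function(matrix, labels) {
  stopifnot(inherits(matrix, "region_matrix"))
  apply(matrix$values, 2L, hand_till_auc, labels = labels)
}

# Shannon entropy (bits) of a label vector.
.label_entropy <- function(labels) {
  p <- tabulate(labels) / length(labels)
  p <- p[p > 0]
  -sum(p * log2(p))
}

# One Fayyad-Irani recursion step on indices ord (values pre-sorted).
.mdl_split <- function(values, labels) {
  n <- length(values)
  if (n < 2L) return(numeric(0))
  o <- order(values)
  v <- values[o]; y <- droplevels(labels[o])
  if (length(levels(y)) < 2L || v[1L] == v[n]) return(numeric(0))
  ent_s <- .label_entropy(y)
  k <- length(levels(y))
  # candidate cuts: midpoints between distinct consecutive values
  distinct <- which(diff(v) > 0)
  best <- NULL
  for (i in distinct) {
    y1 <- y[seq_len(i)]; y2 <- y[(i + 1L):n]
    e1 <- .label_entropy(droplevels(y1)); e2 <- .label_entropy(droplevels(y2))
    went <- (i * e1 + (n - i) * e2) / n
    if (is.null(best) || went < best$went) {
      best <- list(i = i, went = went, e1 = e1, e2 = e2,
                   k1 = length(unique(y1)), k2 = length(unique(y2)))
    }
  }
  gain <- ent_s - best$went
  delta <- log2(3^k - 2) - (k * ent_s - best$k1 * best$e1 - best$k2 * best$e2)
  if (gain <= (log2(n - 1) + delta) / n) return(numeric(0))
  cut <- (v[best$i] + v[best$i + 1L]) / 2
  left <- values <= cut
  c(.mdl_split(values[left], labels[left]), cut,
    .mdl_split(values[!left], labels[!left]))
}

#' Fayyad-Irani MDL supervised discretization
#'
#' Recursive entropy-minimizing binary splitting of a numeric attribute,
#' where each split is accepted only if its information gain exceeds the
#' minimum-description-length criterion
#' \eqn{gain > (\log_2(N-1) + \Delta)/N} with
#' \eqn{\Delta = \log_2(3^k - 2) - [k\,Ent(S) - k_1 Ent(S_1) - k_2 Ent(S_2)]}.
#' May return zero cut points (attribute judged uninformative).
#'
#' @param values numeric attribute.
#' @param labels class labels.
#' @return sorted numeric vector of cut points (possibly empty).
#' @export
mdl_discretize <- function(values, labels) {
  labels <- factor(labels)
  if (length(values) != length(labels)) stop("values/labels length mismatch")
  sort(.mdl_split(values, labels))
}

#' Chi-squared score of an MDL-discretized attribute
#'
#' Pearson Chi-squared statistic of the contingency table formed by the
#' MDL-discretized attribute bins against the class labels. Attributes for
#' which MDL finds no cut score 0 (no evidence of class association).
#'
#' @param values numeric attribute.
#' @param labels class labels.
#' @param cuts optional pre-computed cut points; default runs
#'   [mdl_discretize()].
#' @return Chi-squared statistic (>= 0).
#' @export
chi_squared_score <- function(values, labels, cuts = NULL) {
  labels <- factor(labels)
  if (is.null(cuts)) cuts <- mdl_discretize(values, labels)
  if (!length(cuts)) return(0)
  bins <- cut(values, breaks = c(-Inf, cuts, Inf))
  tab <- table(bins, labels)
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - e)^2 / e)
}

#' Chi-squared scores for every region of a matrix
#' @inheritParams auc_scores
#' @return named numeric vector of Chi-squared statistics per region id.
#' @export
chi2_scores <- function(matrix, labels) {
  stopifnot(inherits(matrix, "region_matrix"))
  apply(matrix$values, 2L, chi_squared_score, labels = labels)
}

#' Principal component extraction at a variance threshold
#'
#' Centered (not scaled) PCA of the samples-by-regions matrix; IR/LCR are
#' already on a common bit scale, so scaling would distort hotspot
#' magnitudes. Retains the smallest number of leading components whose
#' cumulative explained-variance fraction reaches the threshold.
#'
#' @param matrix a [region_matrix()] or numeric matrix (samples x features).
#' @param variance_threshold fraction in (0, 1\]; default 0.80.
#' @return object of class `pca_model`: list(rotation, center, sdev,
#'   var_frac, n_retained, scores) where `scores` holds the retained sample
#'   coordinates.
#' @export
pca_extract <- function(matrix, variance_threshold = 0.80) {
  if (inherits(matrix, "region_matrix")) matrix <- matrix$values
  if (variance_threshold <= 0 || variance_threshold > 1) {
    stop("variance_threshold must be in (0, 1]")
  }
  if (nrow(matrix) < 2L) stop("need at least 2 samples")
  pc <- prcomp(matrix, center = TRUE, scale. = FALSE)
  var_frac <- pc$sdev^2 / sum(pc$sdev^2)
  k <- which(cumsum(var_frac) >= variance_threshold - 1e-12)[1L]
  structure(list(rotation = pc$rotation, center = pc$center, sdev = pc$sdev,
                 var_frac = var_frac, n_retained = k,
                 scores = pc$x[, seq_len(k), drop = FALSE]),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("<pca_model> %d component(s) retained (%.1f%% variance)\n",
              x$n_retained, 100 * sum(x$var_frac[seq_len(x$n_retained)])))
  invisible(x)
}

#' Project new samples onto a fitted PCA
#' @param object a `pca_model`.
#' @param newdata samples x features matrix on the training feature set.
#' @param ... unused.
#' @export
predict.pca_model <- function(object, newdata, ...) {
  sweep(as.matrix(newdata), 2L, object$center) %*%
    object$rotation[, seq_len(object$n_retained), drop = FALSE]
}

#' Select regions by correlation with leading principal components
#'
#' Ranks regions by the maximum absolute Pearson correlation between the
#' region's column and the sample scores of the first `n_components`
#' retained PCs (sign ignored: loadings' orientation is arbitrary). Either
#' the `top_k` best regions or all regions above `threshold` are returned.
#'
#' @param matrix a [region_matrix()].
#' @param n_components number of leading PCs to correlate against.
#' @param top_k number of regions to keep (mutually exclusive with
#'   `threshold`).
#' @param threshold minimum |correlation| to keep.
#' @param pca optional pre-fitted [pca_extract()] model.
#' @return character vector of selected region ids, with the correlation
#'   scores in attribute `"score"`.
#' @export
select_by_pc_correlation <- function(matrix, n_components = 3, top_k = NULL,
                                     threshold = NULL, pca = NULL) {
  stopifnot(inherits(matrix, "region_matrix"))
  if (is.null(top_k) == is.null(threshold)) {
    stop("give exactly one of top_k or threshold")
  }
  if (is.null(pca)) pca <- pca_extract(matrix)
  if (n_components > pca$n_retained) {
    stop("n_components exceeds the ", pca$n_retained, " retained component(s)")
  }
  sc <- pca$scores[, seq_len(n_components), drop = FALSE]
  cors <- abs(cor(matrix$values, sc))
  score <- apply(cors, 1L, max)
  score[is.na(score)] <- 0 # constant regions
  if (!is.null(top_k)) {
    sel <- names(sort(score, decreasing = TRUE))[seq_len(min(top_k, length(score)))]
  } else {
    sel <- names(score)[score >= threshold]
  }
  structure(sel, score = score[sel])
}

#' Discriminatory-power ratio of LCR to IR Chi-squared scores
#'
#' Per-region ratio \eqn{\chi^2_{LCR} / \chi^2_{IR}}: values above 1 tilt
#' the region's discriminatory power toward its SNP content, below 1 toward
#' its methylation content. Regions with \eqn{\chi^2_{IR} = 0} yield NA
#' (flagged, excluded from summaries).
#'
#' @param chi2_lcr,chi2_ir named numeric score vectors over the same region
#'   set (any order).
#' @return named numeric vector of ratios (NA where undefined).
#' @export
discriminatory_power_ratio <- function(chi2_lcr, chi2_ir) {
  if (!setequal(names(chi2_lcr), names(chi2_ir))) {
    stop("region sets differ between the two score vectors")
  }
  chi2_ir <- chi2_ir[names(chi2_lcr)]
  out <- ifelse(chi2_ir == 0, NA_real_, chi2_lcr / chi2_ir)
  names(out) <- names(chi2_lcr)
  out
}

#' Write a feature-score table as TSV
#' @param scores data.frame (or named vectors assembled by the caller) with
#'   a region_id column.
#' @param path output path.
#' @export
write_feature_scores <- function(scores, path) {
  write.table(scores, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
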
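# Compact C-SVC via sequential minimal optimization (SMO).
#
# Self-contained because no SVM library ships with the target environment.
# Deterministic: the second working-set index is chosen by maximal
# |E_i - E_j| rather than at random. Defaults mirror the common libsvm
# conventions: features scaled to zero mean / unit variance, RBF kernel with
# gamma = 1/n_features, C = 1. One-vs-one voting handles multiclass.

.kernel_matrix <- function(X, Y, kernel, gamma) {
  if (kernel == "linear") return(X %*% t(Y))
  # RBF
  d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * X %*% t(Y)
  exp(-gamma * pmax(d2, 0))
}

# Binary SMO; y in {-1, +1}. Returns alpha and b.
.smo_binary <- function(K, y, C, tol = 1e-3, max_passes = 20, max_iter = 5000) {
  n <- length(y)
  alpha <- numeric(n)
  b <- 0
  passes <- 0L
  iter <- 0L
  fcache <- function() as.numeric(K %*% (alpha * y)) + b
  while (passes < max_passes && iter < max_iter) {
    changed <- 0L
    E <- fcache() - y
    for (i in seq_len(n)) {
      E[i] <- sum(alpha * y * K[, i]) + b - y[i]
      r_i <- E[i] * y[i]
      if ((r_i < -tol && alpha[i] < C) || (r_i > tol && alpha[i] > 0)) {
        j <- which.max(abs(E - E[i]))
        if (j == i) next
        E[j] <- sum(alpha * y * K[, j]) + b - y[j]
        a_i_old <- alpha[i]; a_j_old <- alpha[j]
        if (y[i] != y[j]) {
          L <- max(0, alpha[j] - alpha[i]); H <- min(C, C + alpha[j] - alpha[i])
        } else {
          L <- max(0, alpha[i] + alpha[j] - C); H <- min(C, alpha[i] + alpha[j])
        }
        if (L >= H) next
        eta <- 2 * K[i, j] - K[i, i] - K[j, j]
        if (eta >= 0) next
        alpha[j] <- alpha[j] - y[j] * (E[i] - E[j]) / eta
        alpha[j] <- min(max(alpha[j], L), H)
        if (abs(alpha[j] - a_j_old) < 1e-7) next
        alpha[i] <- alpha[i] + y[i] * y[j] * (a_j_old - alpha[j])
        b1 <- b - E[i] - y[i] * (alpha[i] - a_i_old) * K[i, i] -
          y[j] * (alpha[j] - a_j_old) * K[i, j]
        b2 <- b - E[j] - y[i] * (alpha[i] - a_i_old) * K[i, j] -
          y[j] * (alpha[j] - a_j_old) * K[j, j]
        b <- if (alpha[i] > 0 && alpha[i] < C) b1
             else if (alpha[j] > 0 && alpha[j] < C) b2
             else (b1 + b2) / 2
        changed <- changed + 1L
      }
    }
    passes <- if (changed == 0L) passes + 1L else 0L
    iter <- iter + 1L
  }
  list(alpha = alpha, b = b)
}

#' Fit a support vector classifier
#'
#' C-support vector classification trained by a deterministic SMO solver,
#' with one-vs-one voting for more than two classes. Features are centered
#' and scaled on the training data (constant features get unit scale).
#'
#' @param x samples x features numeric matrix.
#' @param y class labels.
#' @param kernel "rbf" (default) or "linear".
#' @param cost soft-margin penalty C; default 1.
#' @param gamma RBF width; default 1/ncol(x).
#' @return object of class `svm_model`.
#' @export
svm_fit <- function(x, y, kernel = c("rbf", "linear"), cost = 1, gamma = NULL) {
  kernel <- match.arg(kernel)
  x <- as.matrix(x)
  y <- factor(y)
  y <- droplevels(y)
  if (length(levels(y)) < 2L) stop("need at least 2 classes")
  if (is.null(gamma)) gamma <- 1 / ncol(x)
  center <- colMeans(x)
  scale_ <- apply(x, 2L, sd)
  scale_[scale_ == 0 | is.na(scale_)] <- 1
  xs <- sweep(sweep(x, 2L, center), 2L, scale_, "/")
  cls <- levels(y)
  pairs <- utils::combn(cls, 2L, simplify = FALSE)
  models <- lapply(pairs, function(pr) {
    sel <- y %in% pr
    Xp <- xs[sel, , drop = FALSE]
    yp <- ifelse(y[sel] == pr[1L], 1, -1)
    K <- .kernel_matrix(Xp, Xp, kernel, gamma)
    fit <- .smo_binary(K, yp, cost)
    sv <- fit$alpha > 1e-8
    list(pair = pr, X = Xp[sv, , drop = FALSE],
         coef = (fit$alpha * yp)[sv], b = fit$b)
  })
  structure(list(models = models, classes = cls, kernel = kernel,
                 gamma = gamma, cost = cost, center = center,
                 scale = scale_),
            class = "svm_model")
}

#' Predict classes from a fitted SVM
#' @param object an `svm_model`.
#' @param newdata samples x features matrix.
#' @param ... unused.
#' @return factor of predicted classes.
#' @export
predict.svm_model <- function(object, newdata, ...) {
  xs <- sweep(sweep(as.matrix(newdata), 2L, object$center), 2L,
              object$scale, "/")
  votes <- matrix(0, nrow(xs), length(object$classes),
                  dimnames = list(NULL, object$classes))
  for (m in object$models) {
    if (nrow(m$X) == 0L) { # degenerate sub-problem: abstain
      next
    }
    dec <- as.numeric(.kernel_matrix(xs, m$X, object$kernel, object$gamma) %*%
                        m$coef) + m$b
    win <- ifelse(dec >= 0, m$pair[1L], m$pair[2L])
    for (k in seq_len(nrow(xs))) {
      votes[k, win[k]] <- votes[k, win[k]] + 1
    }
  }
  factor(object$classes[max.col(votes, ties.method = "first")],
         levels = object$classes)
}
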
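# Independent oracles and fixture builders shared by the suite.
# The oracles deliberately reimplement the statistics by brute force and
# must stay independent of the package code paths they check.

# Count-based methylome sample at fixed coverage from exact levels.
make_meth_sample <- function(id, pos, levels, coverage = 10, chrom = "chr1",
                             strand = "+") {
  meth <- as.integer(round(levels * coverage))
  methylome_sample(id, data.frame(
    chrom = chrom, pos = as.integer(pos), strand = strand, context = "CG",
    meth_reads = meth, total_reads = as.integer(rep(coverage, length(pos))),
    stringsAsFactors = FALSE
  ))
}

make_snp_sample <- function(id, pos, r, concordance, chrom = "chr1",
                            quality = 30) {
  n <- length(pos)
  snp_sample(id, data.frame(
    chrom = rep(chrom, n), pos = as.integer(pos),
    ref_base = rep("A", n), alt_base = rep("G", n),
    quality = rep(quality, n), r = as.integer(r),
    concordance = as.numeric(concordance), stringsAsFactors = FALSE
  ))
}

# Binary entropy, written independently (log base 2).
oracle_entropy <- function(p) {
  out <- numeric(length(p))
  for (i in seq_along(p)) {
    h <- 0
    if (p[i] > 0) h <- h - p[i] * log(p[i], 2)
    if (p[i] < 1) h <- h - (1 - p[i]) * log(1 - p[i], 2)
    out[i] <- h
  }
  out
}

# Brute-force IR: explicit loop over regions and shared sites.
oracle_ir <- function(subject, reference, partition, min_coverage = 1) {
  out <- setNames(numeric(nrow(partition)), partition$region_id)
  a <- subject$sites
  b <- reference$sites
  for (k in seq_len(nrow(partition))) {
    lo <- partition$start[k]; hi <- partition$end[k]; ch <- partition$chrom[k]
    acc <- 0
    for (i in seq_len(nrow(a))) {
      if (a$chrom[i] != ch) next
      p0 <- a$pos[i] - 1
      if (p0 < lo || p0 >= hi) next
      j <- which(b$chrom == a$chrom[i] & b$pos == a$pos[i] &
                   b$strand == a$strand[i])
      if (length(j) != 1L) next
      if (a$total_reads[i] < min_coverage || b$total_reads[j] < min_coverage) next
      acc <- acc + oracle_entropy(b$level[j]) - oracle_entropy(a$level[i])
    }
    out[k] <- acc
  }
  out
}

# Brute-force orientation-free pairwise rank AUC by pair counting.
oracle_pair_auc <- function(x, y) {
  wins <- 0
  for (xi in x) for (yj in y) {
    if (xi > yj) wins <- wins + 1
    else if (xi == yj) wins <- wins + 0.5
  }
  a <- wins / (length(x) * length(y))
  max(a, 1 - a)
}

oracle_hand_till <- function(values, labels) {
  labels <- factor(labels)
  cls <- levels(droplevels(labels))
  tot <- 0; np <- 0
  for (i in seq_len(length(cls) - 1)) {
    for (j in (i + 1):length(cls)) {
      tot <- tot + oracle_pair_auc(values[labels == cls[i]],
                                   values[labels == cls[j]])
      np <- np + 1
    }
  }
  tot / np
}

# Naive UPGMA agglomerator; returns the cophenetic matrix of merge heights
# (ultrametric scale: distance / 2) in input leaf order.
oracle_upgma_cophenetic <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  members <- lapply(seq_len(n), identity)
  sizes <- rep(1, n)
  D <- d
  coph <- matrix(0, n, n)
  while (nrow(D) > 1) {
    m <- nrow(D)
    best <- c(NA, NA); bd <- Inf
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
      if (D[i, j] < bd) { bd <- D[i, j]; best <- c(i, j) }
    }
    i <- best[1]; j <- best[2]
    h <- bd / 2
    for (a in members[[i]]) for (b in members[[j]]) {
      coph[a, b] <- h; coph[b, a] <- h
    }
    newd <- (sizes[i] * D[i, ] + sizes[j] * D[j, ]) / (sizes[i] + sizes[j])
    keep <- setdiff(seq_len(m), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], newd[keep]),
                c(newd[keep], 0))
    members <- c(members[keep], list(c(members[[i]], members[[j]])))
    sizes <- c(sizes[keep], sizes[i] + sizes[j])
    D <- D2
  }
  coph
}

# Random symmetric zero-diagonal distance matrix with distinct entries.
random_dist_matrix <- function(n, labels = paste0("L", seq_len(n))) {
  pts <- matrix(rnorm(n * 3), n, 3)
  m <- as.matrix(dist(pts))
  dimnames(m) <- list(labels, labels)
  m
}
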
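# Region-level information statistics: IR (information gain/loss of
# methylation changes) and LCR (SNP-fixation uncertainty), plus the
# HMR/VMR/LMR region taxonomy.

#' Shannon entropy of a methylation level
#'
#' Binary entropy of the per-site methylation status, in bits:
#' \deqn{H(p) = -p \log_2 p - (1-p) \log_2 (1-p)}
#' with the continuity convention \eqn{0 \log 0 = 0}. Maximal (1 bit) at
#' p = 0.5; zero at fully methylated or unmethylated sites.
#'
#' @param p methylation level(s) in \[0, 1\].
#' @return entropy in bits, same length as `p`.
#' @examples
#' site_entropy(0.5) # 1 bit
#' site_entropy(c(0, 1)) # both 0
#' @export
site_entropy <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("methylation level outside [0, 1]")
  }
  term <- function(x) ifelse(x == 0, 0, -x * log2(x))
  term(p) + term(1 - p)
}

#' Construct a samples-by-regions statistic matrix
#'
#' The common container for IR and LCR values that all downstream machine
#' learning consumes: a numeric matrix with sample ids on rows and region ids
#' on columns.
#'
#' @param values numeric matrix, rows = samples, columns = regions, with
#'   dimnames set.
#' @param statistic "IR" or "LCR".
#' @param reference_id for IR, the id of the reference ("before") sample.
#' @return object of class `region_matrix`.
#' @export
region_matrix <- function(values, statistic = c("IR", "LCR"),
                          reference_id = NULL) {
  statistic <- match.arg(statistic)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("region matrix requires sample ids (rows) and region ids (columns)")
  }
  if (statistic == "LCR" && any(values < 0)) {
    stop("LCR values must be non-negative")
  }
  structure(list(values = values, statistic = statistic,
                 reference_id = reference_id),
            class = "region_matrix")
}

#' @export
print.region_matrix <- function(x, ...) {
  cat("<region_matrix> ", x$statistic, ": ", nrow(x$values), " samples x ",
      ncol(x$values), " regions",
      if (!is.null(x$reference_id)) paste0(" (reference ", x$reference_id, ")"),
      "\n", sep = "")
  invisible(x)
}

#' @export
dim.region_matrix <- function(x) dim(x$values)

# Per-site entropies of a sample restricted to sites usable for IR.
.sample_site_table <- function(sample, min_coverage) {
  s <- sample$sites
  if (!sample$levels_only && min_coverage > 1) {
    s <- s[s$total_reads >= min_coverage, , drop = FALSE]
  }
  s
}

#' Information gained or lost per region
#'
#' For each region R, the entropy difference between a reference ("before")
#' and a subject ("after") methylome:
#' \deqn{I_R = \sum_{i \in R} H(C_i^{before}) - \sum_{i \in R} H(C_i^{after})}
#' summed over cytosine sites present with at least `min_coverage` reads in
#' both samples (level-only samples bypass the coverage filter). Positive
#' values are information gain (uncertainty reduction) in the subject
#' relative to the reference. Regions with no shared qualifying site get 0
#' and are flagged in the `"empty_regions"` attribute.
#'
#' @param subject,reference [methylome_sample()] objects sharing a coordinate
#'   system.
#' @param partition a [make_partition()] result.
#' @param min_coverage minimum total reads required in both samples for a
#'   site to enter the sum; default 1.
#' @return named numeric vector of IR (bits) per region id, with attribute
#'   `empty_regions`.
#' @export
region_information <- function(subject, reference, partition, min_coverage = 1) {
  stopifnot(inherits(subject, "methylome_sample"),
            inherits(reference, "methylome_sample"),
            min_coverage >= 1)
  ir <- setNames(numeric(nrow(partition)), partition$region_id)
  if (identical(subject$sample_id, reference$sample_id)) {
    warning("subject and reference are the same sample; IR is identically 0")
    attr(ir, "empty_regions") <- partition$region_id
    return(ir)
  }
  a <- .sample_site_table(subject, min_coverage)
  b <- .sample_site_table(reference, min_coverage)
  key_a <- paste(a$chrom, a$pos, a$strand, sep = "\r")
  key_b <- paste(b$chrom, b$pos, b$strand, sep = "\r")
  m <- match(key_a, key_b)
  keep <- !is.na(m)
  a <- a[keep, , drop = FALSE]
  b <- b[m[keep], , drop = FALSE]
  ridx <- assign_to_regions(partition, a$chrom, a$pos)
  ok <- !is.na(ridx)
  if (any(ok)) {
    dH <- site_entropy(b$level[ok]) - site_entropy(a$level[ok])
    sums <- tapply(dH, ridx[ok], sum)
    ir[as.integer(names(sums))] <- as.numeric(sums)
    covered <- unique(ridx[ok])
  } else {
    covered <- integer(0)
  }
  attr(ir, "empty_regions") <- partition$region_id[setdiff(seq_len(nrow(partition)), covered)]
  ir
}

#' SNP-fixation uncertainty per region
#'
#' For each region R, the summed log2 normalized SNP-supporting read counts:
#' \deqn{LC_R = \sum_{i \in R} \log_2(rN_i)} with
#' \eqn{rN_i = r_i \times concordance_i}. Sites with rN < 1 are dropped (a
#' sub-unit normalized count would contribute negative uncertainty, outside
#' the Boltzmann model's support). Regions without qualifying SNPs score 0.
#'
#' @param sample a [snp_sample()] (already quality-filtered at read time).
#' @param partition a [make_partition()] result.
#' @return named numeric vector of LCR (bits) per region id.
#' @export
region_lcr <- function(sample, partition) {
  stopifnot(inherits(sample, "snp_sample"))
  lcr <- setNames(numeric(nrow(partition)), partition$region_id)
  s <- sample$sites
  if (!nrow(s)) return(lcr)
  rN <- s$r * s$concordance
  keep <- rN >= 1
  s <- s[keep, , drop = FALSE]
  rN <- rN[keep]
  if (!nrow(s)) return(lcr)
  ridx <- assign_to_regions(partition, s$chrom, s$pos)
  ok <- !is.na(ridx)
  if (any(ok)) {
    sums <- tapply(log2(rN[ok]), ridx[ok], sum)
    lcr[as.integer(names(sums))] <- as.numeric(sums)
  }
  lcr
}

#' Build an IR region matrix for a set of samples
#'
#' @param samples list of [methylome_sample()] subjects.
#' @param reference the reference [methylome_sample()] ("before" state).
#' @param partition a [make_partition()] result.
#' @param min_coverage see [region_information()].
#' @param include_reference include the reference itself as an all-zero row;
#'   default FALSE.
#' @return a [region_matrix()] with statistic "IR".
#' @export
ir_matrix <- function(samples, reference, partition, min_coverage = 1,
                      include_reference = FALSE) {
  rows <- lapply(samples, region_information, reference = reference,
                 partition = partition, min_coverage = min_coverage)
  ids <- vapply(samples, function(s) s$sample_id, "")
  values <- do.call(rbind, rows)
  rownames(values) <- ids
  if (include_reference) {
    values <- rbind(values,
                    matrix(0, 1, ncol(values),
                           dimnames = list(reference$sample_id, NULL)))
  }
  colnames(values) <- partition$region_id
  region_matrix(values, "IR", reference_id = reference$sample_id)
}

#' Build an LCR region matrix for a set of SNP samples
#'
#' @param samples list of [snp_sample()] objects.
#' @param partition a [make_partition()] result.
#' @return a [region_matrix()] with statistic "LCR".
#' @export
lcr_matrix <- function(samples, partition) {
  rows <- lapply(samples, region_lcr, partition = partition)
  values <- do.call(rbind, rows)
  rownames(values) <- vapply(samples, function(s) s$sample_id, "")
  colnames(values) <- partition$region_id
  region_matrix(values, "LCR")
}

#' Classify regions into HMR / VMR / LMR
#'
#' Regions are labelled by the maximum absolute statistic observed across
#' samples, m: low-variable or constant (LMR, m < t1), variable (VMR,
#' t1 <= m < t2) or highly variable (HMR, m >= t2) methylation regions.
#' The taxonomy is defined for IR matrices; crisp thresholds are a
#' configurable convention (t2 = 10 bits anchors the "|IR| >= 10 bit"
#' exemplar scale of highly variable regions).
#'
#' @param matrix a [region_matrix()].
#' @param t1,t2 thresholds in bits, t1 < t2; defaults 2 and 10.
#' @return factor of labels (levels LMR, VMR, HMR) named by region id, with
#'   attribute `thresholds`.
#' @export
classify_regions <- function(matrix, t1 = 2, t2 = 10) {
  stopifnot(inherits(matrix, "region_matrix"), t1 < t2)
  if (matrix$statistic != "IR") {
    warning("region taxonomy is defined for IR matrices; classifying ",
            matrix$statistic, " values anyway")
  }
  m <- apply(abs(matrix$values), 2L, max)
  lab <- ifelse(m >= t2, "HMR", ifelse(m >= t1, "VMR", "LMR"))
  out <- factor(lab, levels = c("LMR", "VMR", "HMR"))
  names(out) <- colnames(matrix$values)
  attr(out, "thresholds") <- c(t1 = t1, t2 = t2)
  out
}

#' Fraction of sample-region cells exceeding an |IR| threshold
#'
#' The exceedance summary used to gauge how rare highly variable cells are:
#' the percentage of cells of the matrix with |value| at or above the cutoff.
#'
#' @param n_exceed number of exceeding cells (or a [region_matrix()], in
#'   which case cells are counted at `threshold`).
#' @param n_total total number of cells; ignored when a matrix is given.
#' @param threshold cutoff in bits, default 10.
#' @return exceedance percentage.
#' @examples
#' exceedance_percent(12971, 13370 * 9) # ~ 10.78 -> "11%"
#' @export
exceedance_percent <- function(n_exceed, n_total = NULL, threshold = 10) {
  if (inherits(n_exceed, "region_matrix")) {
    v <- n_exceed$values
    return(100 * sum(abs(v) >= threshold) / length(v))
  }
  100 * n_exceed / n_total
}

#' Write / read a region matrix as TSV
#'
#' Header row of region ids, first column of sample ids; values serialized
#' at 12 significant digits (round-trip stable at that precision).
#'
#' @param matrix a [region_matrix()].
#' @param path file path.
#' @rdname region_matrix_io
#' @export
write_region_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "region_matrix"))
  df <- data.frame(sample_id = rownames(matrix$values),
                   signif(matrix$values, 12), check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("sample_id", colnames(matrix$values))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @param statistic statistic tag to attach on read ("IR" or "LCR").
#' @param reference_id optional reference sample id to attach on read.
#' @rdname region_matrix_io
#' @export
read_region_matrix <- function(path, statistic = "IR", reference_id = NULL) {
  df <- read.delim(path, header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  values <- as.matrix(df[, -1L, drop = FALSE])
  rownames(values) <- df[[1L]]
  region_matrix(values, statistic, reference_id)
}
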
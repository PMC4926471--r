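# File formats and genome partitioning.
#
# Coordinate convention: all on-disk formats are 1-based inclusive (as in the
# source TSV dialects); internally regions are 0-based half-open. Conversion
# happens only at the I/O boundary.

METH_COLS <- c("chrom", "pos", "strand", "context", "meth_reads", "total_reads")
SNP_COLS <- c("chrom", "pos", "ref_base", "alt_base", "quality", "r", "concordance")
CONTEXTS <- c("CG", "CHG", "CHH")

#' Construct a methylome sample
#'
#' A methylome sample is a per-cytosine table of read counts (or, for
#' wiggle-derived tracks, direct methylation levels). Sites are keyed by
#' (chrom, pos, strand); duplicate keys are an error. Strands are never
#' merged: merging would change the per-site methylation level.
#'
#' @param sample_id sample identifier.
#' @param sites data.frame with columns chrom, pos, strand, context,
#'   meth_reads, total_reads. For level-only samples (see `levels_only`),
#'   a `level` column replaces the count columns.
#' @param levels_only logical; TRUE for tracks that report methylation level
#'   directly without read counts (wiggle input). Such samples bypass
#'   coverage filters downstream.
#' @return an object of class `methylome_sample`.
#' @export
methylome_sample <- function(sample_id, sites, levels_only = FALSE) {
  stopifnot(is.character(sample_id), length(sample_id) == 1L)
  sites <- as.data.frame(sites, stringsAsFactors = FALSE)
  if (levels_only) {
    need <- c("chrom", "pos", "strand", "level")
  } else {
    need <- METH_COLS
  }
  miss <- setdiff(need, names(sites))
  if (length(miss)) {
    stop("methylome sample is missing column(s): ", paste(miss, collapse = ", "))
  }
  key <- paste(sites$chrom, sites$pos, sites$strand, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (chrom, pos, strand) keys in sample '", sample_id, "'")
  }
  if (!levels_only) {
    bad <- which(sites$meth_reads > sites$total_reads |
                   sites$meth_reads < 0 | sites$total_reads < 1)
    if (length(bad)) {
      stop("record error at row ", bad[1L],
           ": requires 0 <= meth_reads <= total_reads and total_reads >= 1")
    }
    sites$level <- sites$meth_reads / sites$total_reads
  } else {
    if (any(sites$level < 0 | sites$level > 1)) {
      stop("record error: methylation level outside [0, 1]")
    }
  }
  if (any(sites$pos < 1)) stop("record error: positions must be >= 1")
  structure(
    list(sample_id = sample_id, sites = sites, levels_only = levels_only),
    class = "methylome_sample"
  )
}

#' @export
print.methylome_sample <- function(x, ...) {
  cat("<methylome_sample> ", x$sample_id, ": ", nrow(x$sites), " sites",
      if (x$levels_only) " (levels only)", "\n", sep = "")
  invisible(x)
}

#' Construct a SNP sample
#'
#' @param sample_id sample identifier.
#' @param sites data.frame with columns chrom, pos, ref_base, alt_base,
#'   quality, r (supporting non-repetitive reads), concordance in \[0, 1\].
#' @return an object of class `snp_sample`.
#' @export
snp_sample <- function(sample_id, sites) {
  stopifnot(is.character(sample_id), length(sample_id) == 1L)
  sites <- as.data.frame(sites, stringsAsFactors = FALSE)
  miss <- setdiff(SNP_COLS, names(sites))
  if (length(miss)) {
    stop("SNP sample is missing column(s): ", paste(miss, collapse = ", "))
  }
  key <- paste(sites$chrom, sites$pos, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (chrom, pos) keys in SNP sample '", sample_id, "'")
  }
  bad <- which(sites$concordance < 0 | sites$concordance > 1)
  if (length(bad)) {
    stop("record error at row ", bad[1L], ": concordance outside [0, 1]")
  }
  if (any(sites$r < 0)) stop("record error: negative supporting-read count")
  structure(list(sample_id = sample_id, sites = sites), class = "snp_sample")
}

#' @export
print.snp_sample <- function(x, ...) {
  cat("<snp_sample> ", x$sample_id, ": ", nrow(x$sites), " SNPs\n", sep = "")
  invisible(x)
}

#' Read a per-cytosine methylation TSV
#'
#' Six tab-separated columns, no header: chromosome, 1-based position, strand
#' (+/-), context (CG/CHG/CHH), methylated read count, total read count.
#' Gzip-compressed files are read transparently.
#'
#' @param path file path.
#' @param context_filter methylation context(s) to retain; default "CG".
#'   Use NULL to keep all contexts.
#' @param sample_id defaults to the file name stripped of extensions.
#' @param lenient if TRUE, malformed records are dropped with a warning
#'   instead of raising; default FALSE (reproducibility over convenience).
#' @return a [methylome_sample()].
#' @export
read_methylation_tsv <- function(path, context_filter = "CG",
                                 sample_id = NULL, lenient = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sample_id)) sample_id <- sub("\\.(tsv|txt)(\\.gz)?$", "", basename(path))
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                   colClasses = c("character", "integer", "character",
                                  "character", "integer", "integer"))
  if (ncol(df) != 6L) {
    stop("format error: expected 6 columns in methylation TSV, got ", ncol(df))
  }
  names(df) <- METH_COLS
  bad <- which(!(df$context %in% CONTEXTS) | !(df$strand %in% c("+", "-")) |
                 is.na(df$pos) | df$pos < 1 | is.na(df$meth_reads) |
                 is.na(df$total_reads) | df$meth_reads < 0 |
                 df$total_reads < 1 | df$meth_reads > df$total_reads)
  if (length(bad)) {
    if (lenient) {
      warning("dropping ", length(bad), " malformed record(s), first at line ", bad[1L])
      df <- df[-bad, , drop = FALSE]
    } else {
      stop("record error at line ", bad[1L], " of ", path)
    }
  }
  if (!is.null(context_filter)) {
    df <- df[df$context %in% context_filter, , drop = FALSE]
  }
  rownames(df) <- NULL
  methylome_sample(sample_id, df)
}

#' Write a methylome sample as TSV
#'
#' Inverse of [read_methylation_tsv()]; write-then-read reproduces the sample.
#'
#' @param sample a [methylome_sample()] (count-based).
#' @param path output path; ".gz" suffix triggers gzip compression.
#' @export
write_methylation_tsv <- function(sample, path) {
  stopifnot(inherits(sample, "methylome_sample"))
  if (sample$levels_only) stop("level-only samples have no count TSV form")
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  write.table(sample$sites[METH_COLS], con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a SNP TSV
#'
#' Seven tab-separated columns, no header: chromosome, 1-based position,
#' reference base, substitution base, quality score, number of non-repetitive
#' supporting reads, concordance. Records below the quality cutoff are
#' excluded (default 25, the standard reporting filter for these tables).
#'
#' @param path file path.
#' @param min_quality minimum quality score retained; default 25.
#' @inheritParams read_methylation_tsv
#' @return a [snp_sample()].
#' @export
read_snp_tsv <- function(path, min_quality = 25, sample_id = NULL,
                         lenient = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sample_id)) sample_id <- sub("\\.(tsv|txt)(\\.gz)?$", "", basename(path))
  first <- tryCatch(readLines(path, n = 1L), error = function(e) character())
  if (!length(first)) {
    return(snp_sample(sample_id, data.frame(
      chrom = character(), pos = integer(), ref_base = character(),
      alt_base = character(), quality = numeric(), r = integer(),
      concordance = numeric(), stringsAsFactors = FALSE
    )))
  }
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                   colClasses = c("character", "integer", "character",
                                  "character", "numeric", "integer", "numeric"))
  if (ncol(df) != 7L) {
    stop("format error: expected 7 columns in SNP TSV, got ", ncol(df))
  }
  names(df) <- SNP_COLS
  bad <- which(is.na(df$pos) | df$pos < 1 | is.na(df$quality) |
                 is.na(df$concordance) | df$concordance < 0 |
                 df$concordance > 1 | is.na(df$r) | df$r < 0)
  if (length(bad)) {
    if (lenient) {
      warning("dropping ", length(bad), " malformed record(s), first at line ", bad[1L])
      df <- df[-bad, , drop = FALSE]
    } else {
      stop("record error at line ", bad[1L], " of ", path)
    }
  }
  df <- df[df$quality >= min_quality, , drop = FALSE]
  rownames(df) <- NULL
  snp_sample(sample_id, df)
}

#' Write a SNP sample as TSV
#' @param sample a [snp_sample()].
#' @param path output path; ".gz" suffix triggers gzip compression.
#' @export
write_snp_tsv <- function(sample, path) {
  stopifnot(inherits(sample, "snp_sample"))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  write.table(sample$sites[SNP_COLS], con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a wiggle methylation-level track
#'
#' Supports the UCSC fixedStep and variableStep dialects, mixed freely within
#' one file. Levels must lie in \[0, 1\]; the resulting sample carries levels
#' without read counts and bypasses coverage filtering downstream.
#'
#' @param path wiggle file path.
#' @param sample_id defaults to the file name stripped of extensions.
#' @return a level-only [methylome_sample()].
#' @export
read_wiggle <- function(path, sample_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sample_id)) sample_id <- sub("\\.(wig|wiggle)(\\.gz)?$", "", basename(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^(track|#)", lines)]
  mode <- NULL; chrom <- NULL; start <- NA_integer_; step <- 1L
  pos_acc <- integer(0); lev_acc <- numeric(0); chr_acc <- character(0)
  fixed_i <- 0L
  parse_kv <- function(line) {
    toks <- strsplit(line, "[ \t]+")[[1]][-1]
    kv <- strsplit(toks, "=", fixed = TRUE)
    setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  }
  for (ln in lines) {
    if (startsWith(ln, "variableStep")) {
      kv <- parse_kv(ln); mode <- "variable"; chrom <- kv[["chrom"]]
    } else if (startsWith(ln, "fixedStep")) {
      kv <- parse_kv(ln); mode <- "fixed"; chrom <- kv[["chrom"]]
      start <- as.integer(kv[["start"]])
      step <- if ("step" %in% names(kv)) as.integer(kv[["step"]]) else 1L
      fixed_i <- 0L
    } else {
      if (is.null(mode)) stop("format error: data line before any step declaration")
      if (mode == "variable") {
        toks <- strsplit(ln, "[ \t]+")[[1]]
        pos_acc <- c(pos_acc, as.integer(toks[1L]))
        lev_acc <- c(lev_acc, as.numeric(toks[2L]))
      } else {
        pos_acc <- c(pos_acc, start + fixed_i * step)
        lev_acc <- c(lev_acc, as.numeric(ln))
        fixed_i <- fixed_i + 1L
      }
      chr_acc <- c(chr_acc, chrom)
    }
  }
  if (any(is.na(lev_acc)) || any(lev_acc < 0 | lev_acc > 1)) {
    stop("record error: wiggle level outside [0, 1]")
  }
  methylome_sample(sample_id, data.frame(
    chrom = chr_acc, pos = pos_acc, strand = "+", level = lev_acc,
    stringsAsFactors = FALSE
  ), levels_only = TRUE)
}

#' Partition a genome into consecutive fixed-width regions
#'
#' The partition is the shared coordinate frame for every region statistic:
#' it must be identical across all samples (consistency across samples
#' matters more than any particular width). The last bin on each chromosome
#' may be short. Region ids render the 1-based inclusive interval,
#' "chrom:start-end"; internally coordinates are 0-based half-open.
#'
#' @param chrom_sizes named numeric vector of chromosome lengths (bp), or a
#'   two-column data.frame (chrom, size).
#' @param bin_width region width in bp; default 2000.
#' @return an object of class `region_partition`: data.frame with columns
#'   chrom, start, end (0-based half-open), region_id.
#' @export
make_partition <- function(chrom_sizes, bin_width = 2000) {
  if (is.data.frame(chrom_sizes)) {
    chrom_sizes <- setNames(as.numeric(chrom_sizes[[2L]]),
                            as.character(chrom_sizes[[1L]]))
  }
  if (!length(chrom_sizes)) stop("empty chrom_sizes")
  if (is.null(names(chrom_sizes)) || any(!nzchar(names(chrom_sizes)))) {
    stop("chrom_sizes must be named by chromosome")
  }
  if (bin_width < 1) stop("bin_width must be >= 1")
  parts <- lapply(names(chrom_sizes), function(ch) {
    size <- chrom_sizes[[ch]]
    if (size < 1) stop("chromosome size must be >= 1: ", ch)
    starts <- seq(0, size - 1, by = bin_width)
    ends <- pmin(starts + bin_width, size)
    data.frame(chrom = ch, start = starts, end = ends,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, parts)
  df$region_id <- sprintf("%s:%d-%d", df$chrom, df$start + 1L, df$end)
  rownames(df) <- NULL
  structure(df, class = c("region_partition", "data.frame"))
}

#' Read a two-column chromosome-sizes file
#' @param path whitespace-separated file: chromosome name, length in bp.
#' @return named numeric vector.
#' @export
read_chrom_sizes <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  setNames(as.numeric(df[[2L]]), as.character(df[[1L]]))
}

# Map 1-based positions to the row index of the partition region containing
# them; NA for positions outside every region.
assign_to_regions <- function(partition, chrom, pos) {
  idx <- rep(NA_integer_, length(pos))
  pos0 <- pos - 1L # 0-based
  for (ch in unique(chrom)) {
    rows <- which(partition$chrom == ch)
    if (!length(rows)) next
    sel <- which(chrom == ch)
    j <- findInterval(pos0[sel], partition$start[rows])
    ok <- j >= 1L & pos0[sel] < partition$end[rows][pmax(j, 1L)]
    idx[sel[ok]] <- rows[j[ok]]
  }
  idx
}

#' Read a sample-to-class label table
#'
#' Two tab-separated columns with header: sample_id, label.
#' @param path file path.
#' @return named factor of class labels keyed by sample id.
#' @export
read_labels_tsv <- function(path) {
  df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  setNames(factor(df[[2L]]), df[[1L]])
}

#' Write a sample-to-class label table
#' @param labels named vector/factor keyed by sample id.
#' @param path output path.
#' @export
write_labels_tsv <- function(labels, path) {
  write.table(data.frame(sample_id = names(labels),
                         label = as.character(labels)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
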
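test_that("methylation TSV reading filters contexts and validates records", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chr1\t10\t+\tCG\t3\t10",
               "chr1\t20\t+\tCHG\t1\t5",
               "chr1\t30\t-\tCG\t0\t7"), f)
  s <- read_methylation_tsv(f)
  expect_equal(nrow(s$sites), 2L)
  expect_true(all(s$sites$context == "CG"))
  s_all <- read_methylation_tsv(f, context_filter = NULL)
  expect_equal(nrow(s_all$sites), 3L)

  # meth_reads > total_reads names the offending line
  writeLines(c("chr1\t10\t+\tCG\t3\t10",
               "chr1\t20\t+\tCG\t5\t4"), f)
  expect_error(read_methylation_tsv(f), "line 2")
  expect_warning(s2 <- read_methylation_tsv(f, lenient = TRUE), "malformed")
  expect_equal(nrow(s2$sites), 1L)
})

test_that("methylation TSV round-trips bit-exactly, including gzip", {
  set.seed(7)
  pos <- sort(sample(1:5000, 10))
  cov <- sample(5:40, 10, replace = TRUE)
  s <- methylome_sample("rt", data.frame(
    chrom = "chr2", pos = pos, strand = sample(c("+", "-"), 10, TRUE),
    context = "CG", meth_reads = vapply(cov, function(k) sample(0:k, 1), 1L),
    total_reads = cov, stringsAsFactors = FALSE
  ))
  for (ext in c(".tsv", ".tsv.gz")) {
    f <- withr::local_tempfile(fileext = ext)
    write_methylation_tsv(s, f)
    s2 <- read_methylation_tsv(f, context_filter = NULL, sample_id = "rt")
    cols <- c("chrom", "pos", "strand", "context", "meth_reads", "total_reads")
    expect_identical(s2$sites[cols], s$sites[cols])
  }
})

test_that("context filtering is idempotent", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chr1\t10\t+\tCG\t3\t10", "chr1\t20\t+\tCHH\t1\t5",
               "chr1\t30\t+\tCG\t2\t4"), f)
  once <- read_methylation_tsv(f, context_filter = "CG")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_methylation_tsv(once, f2)
  twice <- read_methylation_tsv(f2, context_filter = "CG", sample_id = once$sample_id)
  expect_identical(twice$sites, once$sites)
})

test_that("SNP TSV applies the quality cutoff and validates concordance", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chr1\t100\tA\tG\t24\t8\t0.9",
               "chr1\t200\tC\tT\t25\t6\t1.0",
               "chr1\t300\tG\tA\t30\t4\t0.5"), f)
  s <- read_snp_tsv(f)
  expect_equal(nrow(s$sites), 2L) # quality >= 25 retained
  expect_equal(s$sites$pos, c(200L, 300L))

  # empty file -> empty sample
  f0 <- withr::local_tempfile(fileext = ".tsv")
  file.create(f0)
  expect_equal(nrow(read_snp_tsv(f0)$sites), 0L)

  # 5 rows, one below cutoff
  writeLines(sprintf("chr1\t%d\tA\tG\t%d\t5\t0.8", 1:5 * 10, c(30, 10, 30, 30, 30)), f)
  expect_equal(nrow(read_snp_tsv(f)$sites), 4L)

  # concordance outside [0, 1]
  writeLines("chr1\t10\tA\tG\t30\t5\t1.2", f)
  expect_error(read_snp_tsv(f), "record error")
})

test_that("wiggle parsing handles both dialects and validates levels", {
  f <- withr::local_tempfile(fileext = ".wig")
  writeLines(c("variableStep chrom=chr1",
               "10\t0.2", "15\t0.8", "22\t1.0"), f)
  s <- read_wiggle(f)
  expect_equal(s$sites$pos, c(10L, 15L, 22L))
  expect_equal(s$sites$level, c(0.2, 0.8, 1.0))
  expect_true(s$levels_only)

  writeLines(c("fixedStep chrom=chr2 start=100 step=1 span=1",
               "0.1", "0.2", "0.3", "0.4"), f)
  s <- read_wiggle(f)
  expect_equal(s$sites$pos, 100:103)

  # mixed dialects in one file
  writeLines(c("fixedStep chrom=chr1 start=5 step=10",
               "0.5", "0.6",
               "variableStep chrom=chr3",
               "7\t0.9"), f)
  s <- read_wiggle(f)
  expect_equal(s$sites$chrom, c("chr1", "chr1", "chr3"))
  expect_equal(s$sites$pos, c(5L, 15L, 7L))

  writeLines(c("variableStep chrom=chr1", "10\t1.5"), f)
  expect_error(read_wiggle(f), "record error")
})

test_that("partition construction covers the genome exactly once", {
  p <- make_partition(c(chr1 = 10000), 2000)
  expect_equal(nrow(p), 5L)
  p <- make_partition(c(chr1 = 10500), 2000)
  expect_equal(nrow(p), 6L)
  expect_equal(p$end[6] - p$start[6], 500)
  expect_equal(p$region_id[1], "chr1:1-2000")

  # Arabidopsis-like chromosome sizes: count equals sum of ceilings
  sizes <- c(Chr1 = 30427671, Chr2 = 19698289, Chr3 = 23459830,
             Chr4 = 18585056, Chr5 = 26975502)
  p <- make_partition(sizes, 2000)
  expect_equal(nrow(p), sum(ceiling(sizes / 2000)))

  # exact cover: union of half-open intervals = [0, size)
  for (ch in names(sizes)[1:2]) {
    sub <- p[p$chrom == ch, ]
    expect_equal(sub$start, c(0, head(sub$end, -1)))
    expect_equal(tail(sub$end, 1), unname(sizes[ch]))
  }
  expect_error(make_partition(numeric(0)), "empty")
  expect_error(make_partition(c(chr1 = 100), bin_width = 0), "bin_width")
})

test_that("duplicate keys and invariant violations are rejected at construction", {
  df <- data.frame(chrom = "chr1", pos = c(10L, 10L), strand = "+",
                   context = "CG", meth_reads = 1L, total_reads = 2L)
  expect_error(methylome_sample("dup", df), "duplicate")
  df <- data.frame(chrom = "chr1", pos = c(10L, 20L), strand = "+",
                   context = "CG", meth_reads = c(3L, 1L), total_reads = c(2L, 2L))
  expect_error(methylome_sample("bad", df), "meth_reads")
})

test_that("label tables round-trip", {
  lab <- setNames(factor(c("A", "A", "B")), c("s1", "s2", "s3"))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_labels_tsv(lab, f)
  expect_equal(read_labels_tsv(f), lab)
})
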
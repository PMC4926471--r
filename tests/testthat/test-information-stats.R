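test_that("site entropy matches the binary entropy function", {
  expect_equal(site_entropy(0.5), 1)
  expect_equal(site_entropy(c(0, 1)), c(0, 0))
  expect_equal(site_entropy(0.25), 0.811278, tolerance = 1e-6)
  expect_error(site_entropy(1.1), "outside")
  expect_error(site_entropy(-0.01), "outside")
  # symmetry H(p) = H(1-p)
  p <- runif(20)
  expect_equal(site_entropy(p), site_entropy(1 - p))
})

test_that("region IR reproduces hand-computed entropy sums", {
  part <- make_partition(c(chr1 = 100), 100)
  # 3 shared sites: reference p = 0.5 (H = 1 each), subject p in {0, 1}
  ref <- make_meth_sample("ref", c(10, 20, 30), c(0.5, 0.5, 0.5))
  sub <- make_meth_sample("sub", c(10, 20, 30), c(0, 1, 0))
  expect_equal(as.numeric(region_information(sub, ref, part)), 3)
  # information loss: reference p = 1, subject p = 0.5 -> -1 bit
  ref1 <- make_meth_sample("ref", 10, 1)
  sub1 <- make_meth_sample("sub", 10, 0.5)
  expect_equal(as.numeric(region_information(sub1, ref1, part)), -1)
})

test_that("IR of a sample against itself is zero and same-id warns", {
  part <- make_partition(c(chr1 = 200), 100)
  s <- make_meth_sample("a", c(10, 150), c(0.3, 0.8))
  s2 <- make_meth_sample("b", c(10, 150), c(0.3, 0.8))
  expect_equal(as.numeric(region_information(s2, s, part)), c(0, 0))
  expect_warning(ir <- region_information(s, s, part), "same sample")
  expect_equal(as.numeric(ir), c(0, 0))
})

test_that("coverage filtering excludes sites missing or shallow in either sample", {
  part <- make_partition(c(chr1 = 100), 100)
  ref <- methylome_sample("ref", data.frame(
    chrom = "chr1", pos = c(10L, 20L), strand = "+", context = "CG",
    meth_reads = c(5L, 1L), total_reads = c(10L, 2L)))
  sub <- methylome_sample("sub", data.frame(
    chrom = "chr1", pos = c(10L, 20L), strand = "+", context = "CG",
    meth_reads = c(0L, 1L), total_reads = c(10L, 10L)))
  # site 20 has only 2 reads in ref: dropped at min_coverage = 5
  expect_equal(as.numeric(region_information(sub, ref, part, min_coverage = 5)), 1)
  # unshared sites never contribute
  sub2 <- make_meth_sample("sub2", 99, 0.5)
  ir <- region_information(sub2, ref, part)
  expect_equal(as.numeric(ir), 0)
  expect_equal(attr(ir, "empty_regions"), "chr1:1-100")
})

test_that("IR equals the brute-force oracle on random toy samples", {
  set.seed(42)
  part <- make_partition(c(chr1 = 2000), 500)
  for (k in 1:20) {
    pos_a <- sort(sample(1:2000, 20))
    pos_b <- sort(sample(1:2000, 20))
    cov <- 10
    a <- make_meth_sample("a", pos_a, sample(0:cov, 20, TRUE) / cov)
    b <- make_meth_sample("b", pos_b, sample(0:cov, 20, TRUE) / cov)
    expect_equal(as.numeric(region_information(a, b, part)),
                 as.numeric(oracle_ir(a, b, part)), tolerance = 1e-12)
    # antisymmetry (up to float association across site orderings)
    expect_equal(as.numeric(region_information(a, b, part)),
                 -as.numeric(region_information(b, a, part)), tolerance = 1e-12)
    # bound: |IR| <= number of shared sites per region
    shared <- intersect(pos_a, pos_b)
    ridx <- findInterval(shared - 1, part$start)
    n_shared <- tabulate(ridx, nbins = nrow(part))
    expect_true(all(abs(region_information(a, b, part)) <= n_shared + 1e-12))
  }
})

test_that("IR is additive over sub-partitions", {
  set.seed(11)
  coarse <- make_partition(c(chr1 = 2000), 1000)
  fine <- make_partition(c(chr1 = 2000), 250)
  a <- make_meth_sample("a", sort(sample(1:2000, 40)), runif(40))
  b <- make_meth_sample("b", a$sites$pos, runif(40))
  ir_c <- region_information(a, b, coarse)
  ir_f <- region_information(a, b, fine)
  grp <- findInterval(fine$start, coarse$start)
  expect_equal(as.numeric(ir_c), as.numeric(tapply(ir_f, grp, sum)),
               tolerance = 1e-12)
})

test_that("LCR sums log2 normalized counts with the rN >= 1 rule", {
  part <- make_partition(c(chr1 = 200), 100)
  # no SNPs -> 0
  empty <- make_snp_sample("e", integer(0), integer(0), numeric(0))
  expect_equal(as.numeric(region_lcr(empty, part)), c(0, 0))
  # one SNP, r = 8, concordance = 1 -> log2 8 = 3
  s <- make_snp_sample("s", 50, 8, 1)
  expect_equal(as.numeric(region_lcr(s, part)), c(3, 0))
  # rN = 4 and 2 -> 2 + 1 = 3
  s2 <- make_snp_sample("s2", c(110, 150), c(8, 4), c(0.5, 0.5))
  expect_equal(as.numeric(region_lcr(s2, part)), c(0, 3))
  # rN < 1 dropped
  s3 <- make_snp_sample("s3", c(10, 20), c(1, 4), c(0.5, 1))
  expect_equal(as.numeric(region_lcr(s3, part)), c(2, 0))
})

test_that("LCR is monotone in any site's normalized count", {
  part <- make_partition(c(chr1 = 100), 100)
  base <- region_lcr(make_snp_sample("x", c(10, 20), c(4, 8), c(1, 1)), part)
  up <- region_lcr(make_snp_sample("x", c(10, 20), c(4, 16), c(1, 1)), part)
  expect_true(up[1] > base[1])
})

test_that("region taxonomy thresholds work and exceedance math is exact", {
  vals <- matrix(c(15, -1, 0, 0, 3, -4), nrow = 2,
                 dimnames = list(c("s1", "s2"), c("r1", "r2", "r3")))
  rm <- region_matrix(vals, "IR", reference_id = "ref")
  cls <- classify_regions(rm, t1 = 2, t2 = 10)
  expect_equal(as.character(cls), c("HMR", "LMR", "VMR"))
  lcr_rm <- region_matrix(abs(vals), "LCR")
  expect_warning(classify_regions(lcr_rm), "taxonomy")
  expect_error(classify_regions(rm, t1 = 5, t2 = 5))

  expect_equal(round(exceedance_percent(12971, 13370 * 9)), 11)
  expect_equal(exceedance_percent(rm, threshold = 10), 100 / 6)
})

test_that("region matrices round-trip through TSV", {
  set.seed(3)
  vals <- matrix(rnorm(12), 3, 4,
                 dimnames = list(paste0("s", 1:3), paste0("chr1:", 1:4, "-x")))
  rm <- region_matrix(vals, "IR", "s1")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_region_matrix(rm, f)
  rm2 <- read_region_matrix(f, "IR", "s1")
  expect_equal(rm2$values, rm$values, tolerance = 1e-11)
  expect_identical(dimnames(rm2$values), dimnames(rm$values))
})

test_that("region matrix validates labels and LCR non-negativity", {
  expect_error(region_matrix(matrix(1, 1, 1)), "ids")
  m <- matrix(-1, 1, 1, dimnames = list("s", "r"))
  expect_error(region_matrix(m, "LCR"), "non-negative")
})
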
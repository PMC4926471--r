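# Synthetic cohort generator.
#
# Emulates the statistical structure the pipeline assumes: a bimodal CG
# methylome baseline, group-structured methylation hotspots (a level shift
# shared by the samples of one group), Poisson read coverage with binomial
# methylation counts, Boltzmann-distributed SNP supporting reads, and an
# FGM-coupled pair (methylation-shift magnitude, SNP intensity) per hotspot
# region so the region-level IR-LCR dependence is tunable. Output files use
# the exact TSV dialects of the I/O module, so the full pipeline runs on
# them unmodified.

#' Simulation configuration
#'
#' Defaults describe a desk-scale structured population: 3 groups of 15
#' samples, 500 regions of 20 CG sites, 20% hotspot regions with a 0.5
#' methylation-level shift, mean coverage 20 reads, 5 expected SNPs per
#' region, Boltzmann law (lambda = 0.9, beta = 0.5 per bit) for SNP
#' support, and no IR-LCR coupling (theta = 0).
#'
#' @param n_groups number of sample groups.
#' @param samples_per_group samples per group.
#' @param n_regions number of genomic regions (single synthetic chromosome).
#' @param sites_per_region CG sites per region.
#' @param hotspot_fraction fraction of regions that are group hotspots.
#' @param hotspot_effect additive methylation-level shift in \[0, 1\]
#'   applied to a hotspot's owner group (clipped into \[0, 1\]).
#' @param coverage_mean Poisson mean read coverage per site (floor 1).
#' @param snp_rate expected SNP count per region (baseline).
#' @param boltzmann named numeric c(lambda_=, beta=) of the SNP-support law.
#' @param theta FGM coupling in \[-1, 1\] between hotspot shift magnitude
#'   and SNP intensity.
#' @param site_spacing bp between consecutive sites; region width is
#'   `sites_per_region * site_spacing` (default 100 bp x 20 = 2 kb).
#' @param seed mandatory RNG seed.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(n_groups = 3, samples_per_group = 15,
                              n_regions = 500, sites_per_region = 20,
                              hotspot_fraction = 0.2, hotspot_effect = 0.5,
                              coverage_mean = 20, snp_rate = 5,
                              boltzmann = c(lambda_ = 0.9, beta = 0.5),
                              theta = 0, site_spacing = 100, seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(n_groups >= 1, samples_per_group >= 1, n_regions >= 1,
            sites_per_region >= 1,
            hotspot_fraction >= 0, hotspot_fraction <= 1,
            hotspot_effect >= 0, hotspot_effect <= 1,
            coverage_mean > 0, snp_rate >= 0,
            boltzmann[["lambda_"]] > 0, boltzmann[["lambda_"]] <= 1,
            boltzmann[["beta"]] > 0, abs(theta) <= 1, site_spacing >= 2)
  structure(as.list(environment()), class = "simulation_config")
}

.sim_partition <- function(config) {
  width <- config$sites_per_region * config$site_spacing
  make_partition(c(chr1 = config$n_regions * width), bin_width = width)
}

# Site coordinates: sites_per_region sites per region, evenly spaced.
.sim_positions <- function(config) {
  width <- config$sites_per_region * config$site_spacing
  region0 <- rep(seq_len(config$n_regions) - 1L, each = config$sites_per_region)
  offset <- rep(seq_len(config$sites_per_region) - 1L, config$n_regions)
  as.integer(region0 * width + offset * config$site_spacing + 1L)
}

# Bimodal CG baseline: most sites near-unmethylated, a heavy minority
# near-fully methylated, as in real CG methylomes.
.sim_baseline <- function(n) {
  high <- runif(n) < 0.4
  ifelse(high, rbeta(n, 8, 1), rbeta(n, 1, 8))
}

.counts_from_levels <- function(levels, coverage_mean) {
  cov <- pmax(rpois(length(levels), coverage_mean), 1L)
  meth <- rbinom(length(levels), cov, levels)
  list(cov = cov, meth = meth)
}

#' Simulate the reference methylome
#'
#' Baseline methylation levels from the bimodal mixture, Poisson coverage
#' (floor 1), binomial methylated counts. Deterministic given the config
#' seed.
#'
#' @param config a [simulation_config()].
#' @return a [methylome_sample()] with id "reference".
#' @export
simulate_reference <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  pos <- .sim_positions(config)
  base <- .sim_baseline(length(pos))
  cts <- .counts_from_levels(base, config$coverage_mean)
  methylome_sample("reference", data.frame(
    chrom = "chr1", pos = pos, strand = "+", context = "CG",
    meth_reads = cts$meth, total_reads = cts$cov, stringsAsFactors = FALSE
  ))
}

#' Simulate a structured cohort with SNPs and ground truth
#'
#' Generates, from one seed: a reference methylome; `n_groups x
#' samples_per_group` subject methylomes in which each hotspot region's
#' owner group carries a methylation-level shift; per-sample SNP tables
#' whose per-SNP support follows the Boltzmann law (support is encoded
#' exactly: r = ceiling(2^LC), concordance = 2^LC / r, so the file-level
#' records regenerate LC bit-exactly); and the simulation truth. Hotspot
#' regions are dealt round-robin to groups. When `theta != 0` the pair
#' (shift magnitude, SNP-intensity multiplier) of each hotspot region is
#' drawn from the FGM copula, coupling the expected IR and LCR at region
#' level.
#'
#' @param config a [simulation_config()].
#' @return list of class `simulated_cohort` with components:
#'   `reference` ([methylome_sample()]), `samples` (list of subjects),
#'   `snp_samples` (list of [snp_sample()]), `labels` (named factor),
#'   `partition`, and `truth` (class `simulation_truth`: per-region hotspot
#'   flags, owner group, applied shift, SNP multiplier, baseline and
#'   shifted site levels, the Boltzmann and copula parameters, and
#'   `lc_draws`, the full set of candidate LC draws including the
#'   zero-atom -- the sample on which the Boltzmann parameters are
#'   recoverable).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  partition <- .sim_partition(config)
  pos <- .sim_positions(config)
  n_sites <- length(pos)
  region_of_site <- rep(seq_len(config$n_regions), each = config$sites_per_region)
  base <- .sim_baseline(n_sites)

  n_hot <- round(config$hotspot_fraction * config$n_regions)
  hot_regions <- sort(sample.int(config$n_regions, n_hot))
  owner <- rep(NA_integer_, config$n_regions)
  owner[hot_regions] <- rep_len(seq_len(config$n_groups), n_hot)

  # FGM-coupled (u, v): u -> shift magnitude, v -> SNP-intensity multiplier
  uv <- if (n_hot > 0) rfgm(n_hot, config$theta) else cbind(u = numeric(0), v = numeric(0))
  shift <- rep(0, config$n_regions)
  snp_mult <- rep(1, config$n_regions)
  shift[hot_regions] <- config$hotspot_effect * (0.5 + uv[, "u"])
  snp_mult[hot_regions] <- 1 + 4 * uv[, "v"]

  # shifted site levels per region (applied only to the owner group)
  shifted <- base + shift[region_of_site]
  n_clip <- sum(shifted > 1 | shifted < 0)
  if (n_clip > 0) {
    warning(n_clip, " site level(s) clipped into [0, 1] by the hotspot shift")
    shifted <- pmin(pmax(shifted, 0), 1)
  }

  groups <- paste0("G", seq_len(config$n_groups))
  sample_ids <- as.vector(t(outer(groups, sprintf("S%02d", seq_len(config$samples_per_group)),
                                  paste, sep = "_")))
  labels <- setNames(factor(rep(groups, each = config$samples_per_group)),
                     sample_ids)

  lam <- config$boltzmann[["lambda_"]]; bet <- config$boltzmann[["beta"]]
  width <- config$sites_per_region * config$site_spacing

  samples <- list(); snp_samples <- list()
  lc_draws <- list() # every candidate LC draw, zero-atom included
  for (si in seq_along(sample_ids)) {
    sid <- sample_ids[si]
    g <- as.integer(labels[sid]) # factor index = group number
    own <- !is.na(owner) & owner == g
    lev <- ifelse(own[region_of_site], shifted, base)
    cts <- .counts_from_levels(lev, config$coverage_mean)
    samples[[sid]] <- methylome_sample(sid, data.frame(
      chrom = "chr1", pos = pos, strand = "+", context = "CG",
      meth_reads = cts$meth, total_reads = cts$cov, stringsAsFactors = FALSE
    ))
    # SNPs: candidate mutational events per region are Poisson with
    # group-modulated intensity; each candidate draws its LC from the FULL
    # Boltzmann law, and only positive draws materialize as SNP records
    # (the zero-atom candidates are the unfixed mutations lambda governs).
    rate <- config$snp_rate * ifelse(own, snp_mult, 1)
    n_cand <- pmin(rpois(config$n_regions, rate), width - 1L)
    rows <- vector("list", sum(n_cand > 0))
    ri <- 0L
    for (r in which(n_cand > 0)) {
      lc_cand <- rboltzmann(n_cand[r], lam, bet)
      lc_draws[[length(lc_draws) + 1L]] <- lc_cand
      lc <- lc_cand[lc_cand > 0]
      k <- length(lc)
      if (k == 0L) next
      # offsets avoiding cytosine coordinates (which sit on spacing grid)
      off <- sample(setdiff(seq_len(width - 1L),
                            (seq_len(config$sites_per_region) - 1L) * config$site_spacing),
                    k)
      rN <- 2^lc
      rr <- ceiling(rN)
      ri <- ri + 1L
      rows[[ri]] <- data.frame(
        chrom = "chr1",
        pos = as.integer((r - 1L) * width + off + 1L),
        ref_base = sample(c("A", "C", "G", "T"), k, replace = TRUE),
        alt_base = sample(c("A", "C", "G", "T"), k, replace = TRUE),
        quality = 25 + rpois(k, 5),
        r = as.integer(rr),
        concordance = rN / rr,
        stringsAsFactors = FALSE
      )
    }
    snp_df <- if (ri > 0) do.call(rbind, rows) else data.frame(
      chrom = character(), pos = integer(), ref_base = character(),
      alt_base = character(), quality = numeric(), r = integer(),
      concordance = numeric(), stringsAsFactors = FALSE
    )
    snp_df <- snp_df[order(snp_df$pos), , drop = FALSE]
    rownames(snp_df) <- NULL
    snp_samples[[sid]] <- snp_sample(sid, snp_df)
  }

  # reference counts drawn last so subject draws do not depend on them
  ref_cts <- .counts_from_levels(base, config$coverage_mean)
  reference <- methylome_sample("reference", data.frame(
    chrom = "chr1", pos = pos, strand = "+", context = "CG",
    meth_reads = ref_cts$meth, total_reads = ref_cts$cov,
    stringsAsFactors = FALSE
  ))

  truth <- structure(list(
    region_id = partition$region_id,
    is_hotspot = !is.na(owner),
    owner_group = ifelse(is.na(owner), NA_character_, groups[owner]),
    shift = shift, snp_multiplier = snp_mult,
    baseline_levels = base, shifted_levels = shifted,
    region_of_site = region_of_site,
    theta = config$theta, boltzmann = config$boltzmann,
    lc_draws = unlist(lc_draws), labels = labels
  ), class = "simulation_truth")

  structure(list(reference = reference, samples = samples,
                 snp_samples = snp_samples, labels = labels,
                 partition = partition, truth = truth, config = config),
            class = "simulated_cohort")
}

#' Analytic expected IR of a region for a group
#'
#' Closed form from the truth: the summed entropy difference between the
#' baseline and the (possibly shifted) site levels the group's samples were
#' generated from. Zero for non-hotspot regions and non-owner groups.
#'
#' @param truth the `truth` component of [simulate_cohort()].
#' @param region region id (or index).
#' @param group group label (e.g. "G1").
#' @return expected IR in bits.
#' @export
expected_ir <- function(truth, region, group) {
  stopifnot(inherits(truth, "simulation_truth"))
  r <- if (is.character(region)) match(region, truth$region_id) else as.integer(region)
  if (is.na(r) || r < 1 || r > length(truth$region_id)) stop("region not in truth")
  if (!truth$is_hotspot[r] || !identical(truth$owner_group[r], as.character(group))) {
    return(0)
  }
  sel <- truth$region_of_site == r
  sum(site_entropy(truth$baseline_levels[sel]) -
        site_entropy(truth$shifted_levels[sel]))
}

#' Write a simulated cohort to disk
#'
#' Emits the methylation TSVs (reference + subjects), SNP TSVs, the label
#' table and a truth JSON under `dir`, in the exact dialects the readers
#' expect.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "simulated_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "methylomes"), showWarnings = FALSE)
  dir.create(file.path(dir, "snps"), showWarnings = FALSE)
  write_methylation_tsv(cohort$reference,
                        file.path(dir, "methylomes", "reference.tsv"))
  for (s in cohort$samples) {
    write_methylation_tsv(s, file.path(dir, "methylomes", paste0(s$sample_id, ".tsv")))
  }
  for (s in cohort$snp_samples) {
    write_snp_tsv(s, file.path(dir, "snps", paste0(s$sample_id, ".tsv")))
  }
  write_labels_tsv(cohort$labels, file.path(dir, "labels.tsv"))
  tr <- cohort$truth
  jsonlite::write_json(list(
    region_id = tr$region_id, is_hotspot = tr$is_hotspot,
    owner_group = tr$owner_group, shift = tr$shift,
    snp_multiplier = tr$snp_multiplier, theta = tr$theta,
    boltzmann = as.list(tr$boltzmann)
  ), file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA, na = "null")
  # chromosome sizes for partition reconstruction
  width <- cohort$config$sites_per_region * cohort$config$site_spacing
  writeLines(sprintf("chr1\t%d", cohort$config$n_regions * width),
             file.path(dir, "chrom.sizes"))
  invisible(dir)
}
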
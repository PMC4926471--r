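# Pipeline orchestration: every analysis stage as a subcommand driven by a
# single JSON config, with per-stage seeds derived deterministically from
# one global seed.

#' Default pipeline configuration
#'
#' Printed-convention defaults: SNP quality cutoff 25, PCA variance 80%,
#' 7000 Mantel permutations, 1000 x 10-fold cross-validation, CG context,
#' 2 kb regions. All overridable via the config file.
#'
#' @return nested list of defaults.
#' @export
default_pipeline_config <- function() {
  list(
    paths = list(data_dir = "data", out_dir = "out"),
    context = "CG",
    bin_width = 2000,
    min_coverage = 1,
    min_quality = 25,
    taxonomy = list(t1 = 2, t2 = 10),
    chains = list("auc+pca+lda"),
    auc_min = 0.8,
    pca_var = 0.8,
    cv = list(repeats = 1000, folds = 10),
    mantel_permutations = 7000,
    copula = list(theta_method = "spearman"),
    sim = list(n_groups = 3, samples_per_group = 15, n_regions = 500,
               sites_per_region = 20, hotspot_fraction = 0.2,
               hotspot_effect = 0.5, coverage_mean = 20, snp_rate = 5,
               boltzmann = list(lambda_ = 0.9, beta = 0.5), theta = 0),
    seed = 1
  )
}

# Recursively overlay user values on defaults.
.merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]])) {
      base[[nm]] <- .merge_config(base[[nm]], user[[nm]])
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

#' Read a pipeline config file (JSON), filling defaults
#' @param path JSON config path; NULL returns the defaults.
#' @return complete config list.
#' @export
read_pipeline_config <- function(path = NULL) {
  cfg <- default_pipeline_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    cfg <- .merge_config(cfg, jsonlite::read_json(path, simplifyVector = FALSE))
  }
  cfg
}

#' Derive a per-stage seed from the global seed
#'
#' `seed + sum(i * ascii(stage)[i])`, reduced modulo 2^31 - 1 (kept
#' positive), so each stage is independently reproducible from the config
#' alone.
#'
#' @param seed global integer seed.
#' @param stage stage name.
#' @return integer seed < 2^31.
#' @export
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) + h) %% 2147483647 + 1)
}

.plog <- function(cfg, ...) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S"), " [methylDI] ", ...)
  message(msg)
  logf <- file.path(cfg$paths$out_dir, "pipeline.log")
  if (dir.exists(dirname(logf))) cat(msg, "\n", file = logf, append = TRUE)
}

.need <- function(path, producer) {
  if (!file.exists(path)) {
    stop("missing input '", path, "'; run the '", producer,
         "' subcommand first", call. = FALSE)
  }
  path
}

.read_cohort_inputs <- function(cfg) {
  dd <- cfg$paths$data_dir
  sizes <- read_chrom_sizes(.need(file.path(dd, "chrom.sizes"), "simulate"))
  partition <- make_partition(sizes, cfg$bin_width)
  meth_dir <- .need(file.path(dd, "methylomes"), "simulate")
  files <- list.files(meth_dir, pattern = "\\.tsv(\\.gz)?$", full.names = TRUE)
  samples <- lapply(files, read_methylation_tsv, context_filter = cfg$context)
  names(samples) <- vapply(samples, function(s) s$sample_id, "")
  ref <- samples[["reference"]]
  if (is.null(ref)) stop("no 'reference' methylome found in ", meth_dir)
  list(partition = partition,
       reference = ref,
       subjects = samples[names(samples) != "reference"])
}

#' Run a pipeline subcommand
#'
#' Subcommands: `simulate`, `ir`, `lcr`, `classify-regions`, `select`,
#' `fit-chain`, `cv`, `cluster`, `mantel`, `boltzmann`, `copula`,
#' `run-all`. Each reads its inputs from the configured directories, writes
#' its declared TSV/Newick/key-value outputs under `paths$out_dir`, and
#' logs to stderr plus `pipeline.log` (with the effective config serialized
#' alongside and its md5 recorded). Missing stage inputs raise an error
#' naming the producing subcommand. All randomness flows from the single
#' config seed through [stage_seed()].
#'
#' @param subcommand one of the names above.
#' @param config a config list ([read_pipeline_config()]) or a JSON path.
#' @return invisibly, a named list of the artifact paths written.
#' @export
run_pipeline <- function(subcommand, config = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (is.null(config)) config <- default_pipeline_config()
  cfg <- .merge_config(default_pipeline_config(), config)
  cmds <- c("simulate", "ir", "lcr", "classify-regions", "select",
            "fit-chain", "cv", "cluster", "mantel", "boltzmann", "copula",
            "run-all")
  if (!subcommand %in% cmds) {
    stop("unknown subcommand '", subcommand, "'; expected one of: ",
         paste(cmds, collapse = ", "))
  }
  od <- cfg$paths$out_dir
  dir.create(od, recursive = TRUE, showWarnings = FALSE)
  eff <- file.path(od, "effective_config.json")
  jsonlite::write_json(cfg, eff, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  .plog(cfg, "subcommand=", subcommand, " seed=", cfg$seed,
        " config_md5=", unname(tools::md5sum(eff)),
        " R=", getRversion())

  if (subcommand == "run-all") {
    out <- list()
    for (cmd in c("simulate", "ir", "lcr", "classify-regions", "select",
                  "fit-chain", "cv", "cluster", "mantel", "boltzmann",
                  "copula")) {
      out <- c(out, run_pipeline(cmd, cfg))
    }
    return(invisible(out))
  }

  paths <- list()
  if (subcommand == "simulate") {
    sim <- cfg$sim
    sc <- simulation_config(
      n_groups = sim$n_groups, samples_per_group = sim$samples_per_group,
      n_regions = sim$n_regions, sites_per_region = sim$sites_per_region,
      hotspot_fraction = sim$hotspot_fraction,
      hotspot_effect = sim$hotspot_effect,
      coverage_mean = sim$coverage_mean, snp_rate = sim$snp_rate,
      boltzmann = c(lambda_ = sim$boltzmann$lambda_, beta = sim$boltzmann$beta),
      theta = sim$theta, seed = stage_seed(cfg$seed, "simulate")
    )
    cohort <- simulate_cohort(sc)
    write_cohort(cohort, cfg$paths$data_dir)
    paths$data_dir <- cfg$paths$data_dir
  } else if (subcommand == "ir") {
    inp <- .read_cohort_inputs(cfg)
    rm_ir <- ir_matrix(inp$subjects, inp$reference, inp$partition,
                       min_coverage = cfg$min_coverage)
    paths$ir_matrix <- write_region_matrix(rm_ir, file.path(od, "ir_matrix.tsv"))
  } else if (subcommand == "lcr") {
    dd <- cfg$paths$data_dir
    sizes <- read_chrom_sizes(.need(file.path(dd, "chrom.sizes"), "simulate"))
    partition <- make_partition(sizes, cfg$bin_width)
    snp_dir <- .need(file.path(dd, "snps"), "simulate")
    files <- list.files(snp_dir, pattern = "\\.tsv(\\.gz)?$", full.names = TRUE)
    snps <- lapply(files, read_snp_tsv, min_quality = cfg$min_quality)
    rm_lcr <- lcr_matrix(snps, partition)
    paths$lcr_matrix <- write_region_matrix(rm_lcr, file.path(od, "lcr_matrix.tsv"))
  } else if (subcommand == "classify-regions") {
    rm_ir <- read_region_matrix(.need(file.path(od, "ir_matrix.tsv"), "ir"), "IR")
    cls <- classify_regions(rm_ir, cfg$taxonomy$t1, cfg$taxonomy$t2)
    df <- data.frame(region_id = names(cls), class = as.character(cls))
    paths$region_classes <- file.path(od, "region_classes.tsv")
    write.table(df, paths$region_classes, sep = "\t", quote = FALSE,
                row.names = FALSE)
  } else if (subcommand == "select") {
    rm_ir <- read_region_matrix(.need(file.path(od, "ir_matrix.tsv"), "ir"), "IR")
    rm_lcr <- read_region_matrix(.need(file.path(od, "lcr_matrix.tsv"), "lcr"), "LCR")
    labels <- read_labels_tsv(.need(file.path(cfg$paths$data_dir, "labels.tsv"),
                                    "simulate"))
    labels <- labels[rownames(rm_ir$values)]
    auc <- auc_scores(rm_ir, labels)
    chi2_ir <- chi2_scores(rm_ir, labels)
    chi2_lcr <- chi2_scores(rm_lcr, labels)[names(chi2_ir)]
    ratio <- discriminatory_power_ratio(chi2_lcr, chi2_ir)
    df <- data.frame(region_id = names(auc), auc = auc, chi2_ir = chi2_ir,
                     chi2_lcr = chi2_lcr, ratio = ratio, row.names = NULL)
    paths$feature_scores <- write_feature_scores(df, file.path(od, "feature_scores.tsv"))
    sel <- names(auc)[auc >= cfg$auc_min]
    paths$selected_regions <- file.path(od, "selected_regions.txt")
    writeLines(sel, paths$selected_regions)
  } else if (subcommand %in% c("fit-chain", "cv", "cluster", "mantel")) {
    rm_ir <- read_region_matrix(.need(file.path(od, "ir_matrix.tsv"), "ir"), "IR")
    labels <- read_labels_tsv(.need(file.path(cfg$paths$data_dir, "labels.tsv"),
                                    "simulate"))
    labels <- labels[rownames(rm_ir$values)]
    if (subcommand == "fit-chain") {
      ch <- classifier_chain(cfg$chains[[1]], auc_min = cfg$auc_min,
                             pca_var = cfg$pca_var)
      fit <- fit_chain(ch, rm_ir, labels)
      if (!is.null(fit$ld_coordinates)) {
        df <- data.frame(sample_id = rownames(fit$ld_coordinates),
                         fit$ld_coordinates, check.names = FALSE)
        paths$ld_coordinates <- file.path(od, "ld_coordinates.tsv")
        write.table(df, paths$ld_coordinates, sep = "\t", quote = FALSE,
                    row.names = FALSE)
      }
    } else if (subcommand == "cv") {
      res <- list()
      for (spec in unlist(cfg$chains)) {
        ch <- classifier_chain(spec, auc_min = cfg$auc_min, pca_var = cfg$pca_var)
        res[[spec]] <- repeated_cv(ch, rm_ir, labels,
                                   n_repeats = cfg$cv$repeats,
                                   n_folds = cfg$cv$folds,
                                   seed = stage_seed(cfg$seed, "cv"))
      }
      paths$cv_table <- file.path(od, "cv_table.tsv")
      write.table(cv_table(res), paths$cv_table, sep = "\t", quote = FALSE,
                  row.names = FALSE)
    } else { # cluster / mantel need LD coordinates for IR and LCR
      rm_lcr <- read_region_matrix(.need(file.path(od, "lcr_matrix.tsv"), "lcr"), "LCR")
      ch <- classifier_chain("pca+lda", pca_var = cfg$pca_var)
      d_ir <- ld_distance_matrix(fit_chain(ch, rm_ir, labels)$ld_coordinates)
      d_lcr <- ld_distance_matrix(fit_chain(ch, rm_lcr, labels)$ld_coordinates)
      if (subcommand == "cluster") {
        paths$ir_tree <- write_newick(upgma(d_ir), file.path(od, "ir_upgma.nwk"))
        paths$lcr_tree <- write_newick(upgma(d_lcr), file.path(od, "lcr_upgma.nwk"))
        paths$ir_dist <- write_distance_matrix(d_ir, file.path(od, "ir_distances.tsv"))
        paths$lcr_dist <- write_distance_matrix(d_lcr, file.path(od, "lcr_distances.tsv"))
      } else {
        mt <- mantel_test(d_ir, d_lcr, n_perm = cfg$mantel_permutations,
                          seed = stage_seed(cfg$seed, "mantel"))
        paths$mantel <- file.path(od, "mantel.tsv")
        write.table(data.frame(r = mt$r, p_value = mt$p_value,
                               method = mt$method, n_perm = mt$n_perm),
                    paths$mantel, sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }
  } else if (subcommand == "boltzmann") {
    dd <- cfg$paths$data_dir
    snp_dir <- .need(file.path(dd, "snps"), "simulate")
    files <- list.files(snp_dir, pattern = "\\.tsv(\\.gz)?$", full.names = TRUE)
    lc <- unlist(lapply(files, function(f) {
      s <- read_snp_tsv(f, min_quality = cfg$min_quality)
      rN <- s$sites$r * s$sites$concordance
      log2(rN[rN >= 1])
    }))
    fit <- fit_boltzmann(lc)
    paths$boltzmann_fit <- write_boltzmann_fit(fit, file.path(od, "boltzmann_fit.txt"))
    pp <- pp_plot_data(lc, fit)
    paths$pp_data <- file.path(od, "pp_data.tsv")
    write.table(pp, paths$pp_data, sep = "\t", quote = FALSE, row.names = FALSE)
  } else if (subcommand == "copula") {
    rm_ir <- read_region_matrix(.need(file.path(od, "ir_matrix.tsv"), "ir"), "IR")
    rm_lcr <- read_region_matrix(.need(file.path(od, "lcr_matrix.tsv"), "lcr"), "LCR")
    common <- intersect(colnames(rm_ir$values), colnames(rm_lcr$values))
    ir <- as.vector(rm_ir$values[, common])
    lcr <- as.vector(rm_lcr$values[, common])
    keep <- lcr > 0 # Weibull marginal needs positive support
    model <- fit_copula_model(ir[keep], lcr[keep],
                              theta_method = cfg$copula$theta_method)
    paths$copula_model <- write_copula_model(model, file.path(od, "copula_model.txt"))
    kd <- kde2d_density(ir[keep], lcr[keep])
    paths$kde_grid <- write_density_grid(kd, file.path(od, "kde2d.tsv"))
  }
  .plog(cfg, "subcommand=", subcommand, " done: ",
        paste(unlist(paths), collapse = ", "))
  invisible(paths)
}
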
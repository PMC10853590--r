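#' Pipeline configuration
#'
#' Collects input paths, analysis thresholds and the seed for a full run.
#' Defaults are the study-calibrated values: site missingness 0.30,
#' individual missingness 0.30, SV missingness 0.20, SV minimum support 3,
#' LD r2 0.5 in 200-kb windows, environmental pruning r2 0.7, 3 RDA axes
#' scanned at a 3 SD cutoff, strong-candidate r2 0.5, 500 trees.
#'
#' @param snp_vcf,env_recent,individuals required input paths (SNP VCF,
#'   recent environmental CSV, individual->population CSV).
#' @param sv_vcf,env_future,bed,gff,grid_csv optional inputs; `env_future`
#'   is a named character vector of scenario CSVs.
#' @param out_dir output directory.
#' @param max_site_missing,max_ind_missing,sv_max_missing,sv_min_support,
#'   ld_r2,ld_window_bp,env_prune_r2,n_axes,sd_cutoff,strong_r2,n_trees,
#'   offset_predictors,keep_priority,exclude_variables analysis settings.
#' @param seed integer seed used for every stochastic stage.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(snp_vcf, env_recent, individuals,
                            sv_vcf = NULL, env_future = c(),
                            bed = NULL, gff = NULL, grid_csv = NULL,
                            out_dir = "landgea_out",
                            max_site_missing = 0.30, max_ind_missing = 0.30,
                            sv_max_missing = 0.20, sv_min_support = 3,
                            ld_r2 = 0.5, ld_window_bp = 200000,
                            env_prune_r2 = 0.7, n_axes = 3, sd_cutoff = 3,
                            strong_r2 = 0.5, n_trees = 500,
                            offset_predictors = "bio5",
                            keep_priority = NULL,
                            exclude_variables = c("surface_area", "pH"),
                            seed = 1) {
  cfg <- as.list(environment())
  in01 <- function(x) is.numeric(x) && length(x) == 1 && x >= 0 && x <= 1
  if (!in01(max_site_missing) || !in01(max_ind_missing) ||
      !in01(sv_max_missing) || !in01(ld_r2) || !in01(env_prune_r2) ||
      !in01(strong_r2))
    stop("missingness and r2 thresholds must lie in [0, 1]")
  if (n_axes < 1) stop("n_axes must be >= 1")
  if (sd_cutoff <= 0) stop("sd_cutoff must be positive")
  if (n_trees < 1) stop("n_trees must be >= 1")
  if (sv_min_support < 0) stop("sv_min_support must be >= 0")
  if (ld_window_bp <= 0) stop("ld_window_bp must be positive")
  for (p in c(snp_vcf, env_recent, individuals, sv_vcf, bed, gff, grid_csv,
              unname(env_future))) {
    if (!is.null(p) && !file.exists(p)) stop("input file not found: ", p)
  }
  class(cfg) <- "pipeline_config"
  cfg
}

write_stage_csv <- function(df, dir, name) {
  path <- file.path(dir, paste0(name, ".csv"))
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Run the full pipeline
#'
#' Executes the stages in analysis order: read + filter SNP (and SV)
#' genotypes, heterozygosity and its environmental associations,
#' imputation and PCA, variance partitioning, the GEA pRDA with outlier
#' detection and environmental assignment, the adaptively enriched RDA
#' and adaptive-index grid (when a grid CSV is supplied), the gradient
#' forest, and genomic offsets per site (plus per ecotype group when
#' ecotypes are labelled). All tabular outputs are CSV files in
#' `config$out_dir`; a JSON manifest records the config, input hashes,
#' seed and stage-wise record counts. Reruns with the same config are
#' byte-identical.
#'
#' @param config a [pipeline_config()].
#' @return named list of output paths plus the in-memory results,
#'   invisibly; the manifest is written as `manifest.json`.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_msg <- function(...) message("[landgea] ", ...)
  counts <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           "\n  counts so far: ",
           paste(names(counts), unlist(counts), sep = "=", collapse = ", "),
           call. = FALSE))
  }
  set.seed(config$seed)
  outputs <- list()

  ## --- variants ------------------------------------------------------
  pops <- utils::read.csv(config$individuals)
  snps <- stage("read_snps", {
    gm <- read_vcf(config$snp_vcf)
    gm <- set_populations(gm, pops)
    gm <- filter_sites(gm, max_site_missing = config$max_site_missing)
    gm <- filter_individuals(gm, max_ind_missing = config$max_ind_missing)
    gm <- ld_prune(gm, r2_threshold = config$ld_r2,
                   window_bp = config$ld_window_bp)
    if (!is.null(config$bed)) gm <- exclude_regions(gm, config$bed)
    gm
  })
  counts$snp_loci <- n_loci(snps); counts$individuals <- n_individuals(snps)
  log_msg("SNPs after filters: ", n_loci(snps), " loci x ",
          n_individuals(snps), " individuals")

  svs <- NULL
  if (!is.null(config$sv_vcf)) {
    svs <- stage("read_svs", {
      gm <- read_vcf(config$sv_vcf, support_field = "SR")
      gm <- set_populations(gm, pops)
      gm <- recode_low_support(gm, min_support = config$sv_min_support)
      gm <- filter_sites(gm, biallelic_only = FALSE,
                         max_site_missing = config$sv_max_missing)
      gm <- filter_individuals(gm, max_ind_missing = config$max_ind_missing)
      gm
    })
    counts$sv_loci <- n_loci(svs)
    log_msg("SVs after filters: ", n_loci(svs), " loci")
  }

  ## --- environment ---------------------------------------------------
  env_raw <- stage("environment", load_env(config$env_recent, "recent"))
  complete_vars <- setdiff(colnames(env_raw$values), env_raw$incomplete)
  env_complete <- env_table(env_raw$values[, complete_vars, drop = FALSE],
                            ids = env_raw$ids, layer = "recent")
  env_pruned <- prune_correlated(env_complete,
                                 r2_threshold = config$env_prune_r2,
                                 keep_priority = config$keep_priority)
  env_std <- standardize_env(env_pruned)
  counts$env_variables <- ncol(env_pruned$values)

  env_future <- lapply(config$env_future, function(p) {
    fut <- load_env(p, "future")
    env_table(fut$values[, colnames(env_pruned$values), drop = FALSE],
              ids = fut$ids, layer = fut$layer)
  })

  ## --- diversity -----------------------------------------------------
  het <- stage("heterozygosity", heterozygosity(snps))
  outputs$heterozygosity <- write_stage_csv(het, config$out_dir,
                                            "heterozygosity")
  assoc <- stage("association", association_table(het, env_complete))
  outputs$association <- write_stage_csv(assoc, config$out_dir,
                                         "association_table")
  counts$associations <- nrow(assoc)

  ## --- ordination + GEA ----------------------------------------------
  gea_res <- stage("gea", run_gea(snps, env_std,
                                  n_axes = config$n_axes,
                                  sd_cutoff = config$sd_cutoff,
                                  strong_r2 = config$strong_r2))
  outputs$outliers <- write_stage_csv(gea_res$outliers, config$out_dir,
                                      "outliers")
  outputs$strong_outliers <- write_stage_csv(gea_res$strong, config$out_dir,
                                             "strong_outliers")
  counts$outliers <- nrow(gea_res$outliers)
  counts$strong_outliers <- nrow(gea_res$strong)
  log_msg("GEA: ", nrow(gea_res$outliers), " candidates, ",
          nrow(gea_res$strong), " strong")

  partition <- stage("partition", {
    geo <- NULL  # geography optional: use grid coordinates when provided
    sets <- list(climate = gea_res$env_individual,
                 structure = gea_res$pcs)
    eco <- snps$individuals$ecotype
    if (length(unique(eco[!is.na(eco)])) > 1) {
      sets$ecotype <- stats::model.matrix(~ factor(eco))[, -1, drop = FALSE]
    }
    partial_rda_variance(gea_res$Y, sets)
  })
  outputs$partition <- write_stage_csv(partition, config$out_dir,
                                       "variance_partition")

  if (!is.null(config$gff) && nrow(gea_res$strong)) {
    genes <- stage("annotation",
                   annotate_nearest_gene(gea_res$strong, config$gff,
                                         snps$loci))
    outputs$nearest_genes <- write_stage_csv(genes, config$out_dir,
                                             "nearest_genes")
  }

  ## --- adaptive landscape --------------------------------------------
  adaptive <- NULL
  climate_vars <- setdiff(colnames(env_std$values), config$exclude_variables)
  if (nrow(gea_res$strong)) {
    adaptive <- stage("adaptive_rda", {
      env4 <- env_table(env_std$values[, climate_vars, drop = FALSE],
                        ids = env_std$ids, layer = "recent",
                        standardization = lapply(env_std$standardization,
                                                 function(p) p[climate_vars]))
      adaptive_enriched_rda(gea_res$gm_imputed, gea_res$strong, env4,
                            gea_res$pcs,
                            exclude_variables = config$exclude_variables)
    })
    if (!is.null(config$grid_csv)) {
      grid_layers <- stage("grid", load_env_grid(config$grid_csv))
      recent_grid <- grid_layers[["recent"]]
      grid_std <- standardize_env(
        env_table(recent_grid$values[, climate_vars, drop = FALSE],
                  ids = recent_grid$ids, layer = "recent"),
        reference = env_table(env_pruned$values[, climate_vars, drop = FALSE],
                              ids = env_pruned$ids))
      attr(grid_std, "coords") <- attr(recent_grid, "coords")
      idx_grid <- do.call(rbind, lapply(
        seq_len(min(2, length(adaptive$eigenvalues))),
        function(ax) adaptive_index(adaptive, ax, grid_std)))
      outputs$adaptive_index <- write_stage_csv(idx_grid, config$out_dir,
                                                "adaptive_index")
      counts$grid_cells <- nrow(recent_grid$values)
    }
  }

  ## --- gradient forest + offset --------------------------------------
  if (nrow(gea_res$strong) && length(env_future)) {
    gf <- stage("gradient_forest", {
      strong_gm <- subset_gm(
        gea_res$gm_unimputed,
        loc_keep = gea_res$gm_unimputed$loci$id %in% gea_res$strong$locus_id)
      freqs <- allele_frequencies(strong_gm)
      fit_gradient_forest(freqs, env_complete$values[freqs$groups, ,
                                                     drop = FALSE],
                          n_trees = config$n_trees,
                          seed = config$seed)
    })
    imp <- data.frame(predictor = names(gf$importance),
                      importance = unname(gf$importance),
                      group = unname(gf$predictor_groups))
    imp <- imp[order(-imp$importance), ]
    outputs$importance <- write_stage_csv(imp, config$out_dir,
                                          "gf_importance")
    counts$gf_retained_loci <- length(gf$retained)
    offs <- lapply(names(env_future), function(sc) {
      off <- stage(paste0("offset_", sc), genomic_offset(
        gf, env_complete, env_future[[sc]],
        predictors = intersect(config$offset_predictors, gf$predictors)))
      off$scenario <- sc
      off
    })
    offsets <- do.call(rbind, offs)
    outputs$offsets <- write_stage_csv(offsets, config$out_dir, "offsets")
    counts$offsets <- nrow(offsets)
    log_msg("offsets computed for ", nrow(offsets), " site x scenario rows")

    eco <- snps$individuals$ecotype
    if (length(env_future) && any(!is.na(eco) & eco != "none")) {
      eco_off <- lapply(names(env_future), function(sc) {
        off <- stage(paste0("ecotype_offset_", sc), ecotype_offsets(
          gea_res$gm_unimputed, gea_res$strong$locus_id,
          env_complete, env_future[[sc]],
          n_trees = config$n_trees, seed = config$seed))
        off$scenario <- sc
        off
      })
      outputs$ecotype_offsets <- write_stage_csv(do.call(rbind, eco_off),
                                                 config$out_dir,
                                                 "ecotype_offsets")
    }
  }

  ## --- manifest -------------------------------------------------------
  inputs <- Filter(Negate(is.null),
                   list(snp_vcf = config$snp_vcf, sv_vcf = config$sv_vcf,
                        env_recent = config$env_recent,
                        individuals = config$individuals,
                        bed = config$bed, gff = config$gff,
                        grid_csv = config$grid_csv))
  manifest <- list(
    seed = config$seed,
    config = config[!vapply(config, is.null, logical(1))],
    input_md5 = as.list(tools::md5sum(unlist(c(inputs,
                                               config$env_future)))),
    counts = counts,
    outputs = outputs)
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  outputs$manifest <- manifest_path
  invisible(list(outputs = outputs, counts = counts, snps = snps, svs = svs,
                 env = env_std, het = het, association = assoc,
                 gea = gea_res, partition = partition,
                 adaptive = adaptive))
}

#' GEA stage: pRDA conditioned on genotype PCs, outliers, assignment
#'
#' Convenience wrapper running the core genotype-environment association
#' sequence on a filtered genotype matrix: mode imputation, PCA for
#' population structure (first `n_pcs` components), partial RDA of
#' dosages on the standardized environmental variables conditioned on the
#' PCs, outlier detection on the leading axes, environmental assignment
#' and strong-candidate subsetting.
#'
#' @param gm filtered, unimputed [genotype_matrix()].
#' @param env_std standardized [env_table()] (rows = populations or
#'   individuals).
#' @param n_pcs number of structure PCs to condition on (default 3).
#' @param n_axes,sd_cutoff,strong_r2 see [detect_outliers()] /
#'   [strong_candidates()].
#' @return list with `rda`, `outliers`, `strong`, `pcs`, `gm_imputed`,
#'   `gm_unimputed`, `Y` (centered dosages) and `env_individual`.
#' @export
run_gea <- function(gm, env_std, n_pcs = 3, n_axes = 3, sd_cutoff = 3,
                    strong_r2 = 0.5) {
  gm_imp <- impute_mode(gm)
  pcs <- pca(gm_imp$dosage, k = n_pcs)$scores
  colnames(pcs) <- paste0("PC", seq_len(ncol(pcs)))
  E <- if (all(gm$individuals$population %in% env_std$ids)) {
    broadcast_env(env_std, gm$individuals$population)
  } else {
    env_std$values[match(gm$individuals$id, env_std$ids), , drop = FALSE]
  }
  fit <- rda(gm_imp$dosage, E, Z = pcs)
  out <- detect_outliers(fit, n_axes = min(n_axes, ncol(fit$loadings)),
                         sd_cutoff = sd_cutoff)
  out <- assign_env(out, gm_imp, env_std)
  strong <- strong_candidates(out, r2_min = strong_r2)
  list(rda = fit, outliers = out, strong = strong, pcs = pcs,
       gm_imputed = gm_imp, gm_unimputed = gm,
       Y = scale(gm_imp$dosage, scale = FALSE), env_individual = E)
}
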
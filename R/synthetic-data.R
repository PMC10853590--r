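#' Generate a gridded environmental landscape
#'
#' Builds a rectangular grid of cells whose recent-period variable values
#' vary linearly along a stated direction (plus optional smooth noise),
#' and one or more future scenario layers defined as additive change
#' fields on top of the recent layer. This emulates bioclim-style raster
#' layers (e.g. maximum temperature of the warmest month, bio5) for a
#' recent baseline and projected emission scenarios.
#'
#' @param n_x,n_y grid dimensions (cells); `n_x * n_y >= 4`.
#' @param gradients named list: variable -> `list(direction = "x"|"y",
#'   range = c(low, high), noise_sd = <optional>)`. Recent values
#'   interpolate linearly from `low` to `high` along the direction; a
#'   per-variable `noise_sd` overrides the global one, so variables
#'   sharing a direction stay correlated without being collinear.
#' @param deltas named list: variable -> named list scenario -> additive
#'   change, given as a scalar, a vector of length `n_x * n_y`, or a
#'   `function(x, y)` evaluated on cell coordinates. Variables without a
#'   delta for a scenario are carried over unchanged.
#' @param noise_sd standard deviation of a smooth (low-frequency) random
#'   field added to each recent variable; 0 (default) for none.
#' @param seed integer seed; the same seed reproduces the grid exactly.
#' @return an object of class `env_grid`: list with `cells` (data frame
#'   `cell_id`, `x`, `y`), `variables`, `recent` (cells x variables
#'   matrix) and `future` (named list of scenario matrices).
#' @export
make_landscape <- function(n_x, n_y, gradients,
                           deltas = list(), noise_sd = 0, seed = 1) {
  if (n_x * n_y < 4) stop("grid must have at least 4 cells")
  unknown <- setdiff(names(deltas), names(gradients))
  if (length(unknown))
    stop("delta specified for unknown variable(s): ",
         paste(unknown, collapse = ", "))
  set.seed(seed)
  cells <- expand.grid(x = seq_len(n_x), y = seq_len(n_y))
  cells <- data.frame(cell_id = sprintf("c%04d", seq_len(nrow(cells))),
                      x = cells$x, y = cells$y)
  vars <- names(gradients)
  recent <- matrix(NA_real_, nrow(cells), length(vars),
                   dimnames = list(cells$cell_id, vars))
  for (v in vars) {
    g <- gradients[[v]]
    t <- switch(g$direction,
                x = if (n_x > 1) (cells$x - 1) / (n_x - 1) else rep(0.5, nrow(cells)),
                y = if (n_y > 1) (cells$y - 1) / (n_y - 1) else rep(0.5, nrow(cells)),
                stop("direction must be 'x' or 'y'"))
    val <- g$range[1] + t * (g$range[2] - g$range[1])
    v_noise <- g$noise_sd %||% noise_sd
    if (v_noise > 0) {
      # smooth low-frequency surface: random combination of slow trig terms
      a <- stats::rnorm(6)
      xn <- (cells$x - 1) / max(1, n_x - 1); yn <- (cells$y - 1) / max(1, n_y - 1)
      field <- a[1] * sin(pi * xn) + a[2] * cos(pi * yn) +
        a[3] * sin(pi * yn) * cos(pi * xn) + a[4] * xn * yn +
        a[5] * sin(2 * pi * xn) + a[6] * cos(2 * pi * yn)
      val <- val + v_noise * field / stats::sd(field)
    }
    recent[, v] <- val
  }
  scenarios <- unique(unlist(lapply(deltas, names)))
  future <- lapply(scenarios, function(sc) {
    fut <- recent
    for (v in names(deltas)) {
      d <- deltas[[v]][[sc]]
      if (is.null(d)) next
      dv <- if (is.function(d)) d(cells$x, cells$y) else d
      fut[, v] <- fut[, v] + dv
    }
    fut
  })
  names(future) <- scenarios
  structure(list(cells = cells, variables = vars,
                 recent = recent, future = future, seed = seed),
            class = "env_grid")
}

#' Default six-variable landscape specification
#'
#' A bioclim-style variable set mirroring the kind retained for lake
#' landscapes after correlation pruning: two temperature variables (bio5,
#' bio6, degrees C) varying with latitude (grid y), two precipitation
#' variables (bio15 seasonality in percent, bio16 wettest-quarter totals
#' in mm) varying with longitude (grid x), lake pH, and log lake surface
#' area (log km2, essentially spatially unstructured). Per-variable noise
#' keeps same-direction variables correlated (as real temperature
#' variables are) without being collinear.
#'
#' @return named list usable as `gradients` in [make_landscape()].
#' @export
default_gradients <- function() {
  list(
    bio5 = list(direction = "y", range = c(20, 35), noise_sd = 3.5),
    bio6 = list(direction = "y", range = c(-18, -2), noise_sd = 4),
    bio15 = list(direction = "x", range = c(30, 80), noise_sd = 12),
    bio16 = list(direction = "x", range = c(250, 600), noise_sd = 90),
    pH = list(direction = "x", range = c(6.8, 8.2), noise_sd = 0.45),
    surface_area = list(direction = "x", range = c(0, 6), noise_sd = 2)
  )
}

#' Default future-scenario change fields
#'
#' Additive warming of bio5 under a best-case (`rcp26`) and worst-case
#' (`rcp85`) scenario. Warming is stronger where the recent climate is
#' cooler (low grid y on the [default_gradients()] landscape), the
#' standard high-latitude amplification pattern, so projected change
#' varies smoothly across the landscape.
#'
#' @return named list usable as `deltas` in [make_landscape()].
#' @export
default_deltas <- function() {
  list(bio5 = list(rcp26 = function(x, y) 1.9 - 0.08 * (y - 1),
                   rcp85 = function(x, y) 6.2 - 0.30 * (y - 1)))
}

#' One-call synthetic study fixture
#'
#' Landscape, population design, SNP panel and SV panel under the
#' package's default study conditions: a 10 x 10 grid with the
#' [default_gradients()] variables and [default_deltas()] scenarios,
#' 20 populations of 10 individuals spanning the bio5 gradient with 3
#' co-occurring stream/shore ecotype pairs and hierarchical neutral
#' structure (F = 0.05 within lineages), 2,000 neutral + 50 adaptive
#' SNPs with |b| in [2, 3] on the standardized bio5 scale, and a
#' 500-locus SV panel with higher missingness.
#'
#' @param seed integer seed driving every stage.
#' @param n_neutral,n_adaptive SNP panel composition.
#' @param n_sv SV panel size.
#' @param causal_variables variables adaptive loci track (default bio5).
#' @return list with `grid`, `design`, `snps`, `svs`.
#' @export
default_fixture <- function(seed = 1, n_neutral = 2000, n_adaptive = 50,
                            n_sv = 500, causal_variables = "bio5") {
  grid <- make_landscape(10, 10, gradients = default_gradients(),
                         deltas = default_deltas(), seed = seed)
  design <- population_design(grid, n_pops = 20, n_individuals = 10,
                              fst = 0.05, ecotype_pairs = 3,
                              seed = seed + 1)
  snps <- simulate_genotypes(design, grid, n_neutral = n_neutral,
                             n_adaptive = n_adaptive,
                             slope_range = c(2, 3),
                             missing_rate = 0.02,
                             causal_variables = causal_variables,
                             seed = seed + 2)
  svs <- simulate_sv_panel(design, grid, n_loci = n_sv,
                           missing_rate = 0.10,
                           causal_variables = causal_variables,
                           seed = seed + 3)
  list(grid = grid, design = design, snps = snps, svs = svs)
}

#' @export
print.env_grid <- function(x, ...) {
  cat("env_grid:", nrow(x$cells), "cells,",
      length(x$variables), "variables,",
      length(x$future), "future scenario(s)\n")
  invisible(x)
}

#' Environmental table for grid cells or sampled populations
#'
#' @param grid an [make_landscape()] grid.
#' @param layer `"recent"` or a scenario name from the grid.
#' @return an [env_table()] over all grid cells with coordinates attached.
#' @export
grid_env_table <- function(grid, layer = "recent") {
  m <- if (layer == "recent") grid$recent else {
    if (!layer %in% names(grid$future)) stop("unknown scenario: ", layer)
    grid$future[[layer]]
  }
  tab <- env_table(m, ids = grid$cells$cell_id,
                   layer = if (layer == "recent") "recent"
                           else paste0("future:", layer))
  attr(tab, "coords") <- data.frame(cell = grid$cells$cell_id,
                                    x = grid$cells$x, y = grid$cells$y)
  tab
}

#' @rdname grid_env_table
#' @param design a [population_design()] table; rows of the returned table
#'   are populations, taking their values from the occupied cells.
#' @export
design_env_table <- function(design, grid, layer = "recent") {
  tab <- grid_env_table(grid, layer)
  idx <- match(design$cell_id, tab$ids)
  env_table(tab$values[idx, , drop = FALSE], ids = design$pop_id,
            layer = tab$layer)
}

#' Place populations on a landscape
#'
#' Populations are placed on distinct cells spanning the environmental
#' gradient (evenly spaced along the sorted values of `span_variable`).
#' Optionally, the first `ecotype_pairs` placements are made as pairs of
#' co-occurring populations on the same cell labelled `"stream"` and
#' `"shore"`, emulating lakes where both reproductive ecotypes spawn.
#'
#' @param grid an [make_landscape()] grid.
#' @param n_pops number of populations (pairs count as two).
#' @param n_individuals individuals per population.
#' @param fst Balding-Nichols differentiation parameter in (0, 1), one
#'   value recycled or a vector per population.
#' @param ecotype_pairs number of co-occurring stream/shore pairs.
#' @param n_lineages number of ancestral lineages populations are
#'   assigned to (at random, independent of their position on the
#'   gradient); neutral loci drift hierarchically, lineage around the
#'   ancestral frequency and population around the lineage, so that
#'   population structure is not confounded with climate.
#' @param lineage_fst differentiation of lineages from the ancestral pool.
#' @param span_variable grid variable along which placements are spread
#'   (default: first grid variable).
#' @param seed integer seed.
#' @return data frame (`pop_id`, `cell_id`, `n_individuals`, `ecotype`,
#'   `lineage`, `fst`, `lineage_fst`), class `population_design`.
#' @export
population_design <- function(grid, n_pops = 20, n_individuals = 10,
                              fst = 0.05, ecotype_pairs = 0,
                              n_lineages = 4, lineage_fst = 0.15,
                              span_variable = grid$variables[1], seed = 1) {
  if (any(fst <= 0 | fst >= 1)) stop("fst must lie in (0, 1)")
  if (2 * ecotype_pairs > n_pops)
    stop("ecotype_pairs exceed available populations")
  set.seed(seed)
  n_cells_needed <- n_pops - ecotype_pairs   # pairs share a cell
  ord <- order(grid$recent[, span_variable])
  pick <- ord[round(seq(1, nrow(grid$cells), length.out = n_cells_needed))]
  pick <- unique(pick)
  if (length(pick) < n_cells_needed)
    stop("grid too small to place ", n_cells_needed, " distinct cells")
  cell_ids <- grid$cells$cell_id[pick]
  pop_cells <- character(n_pops); eco <- rep("none", n_pops)
  k <- 1
  for (i in seq_len(ecotype_pairs)) {
    pop_cells[c(2 * i - 1, 2 * i)] <- cell_ids[k]
    eco[2 * i - 1] <- "stream"; eco[2 * i] <- "shore"
    k <- k + 1
  }
  if (2 * ecotype_pairs < n_pops) {
    rest <- (2 * ecotype_pairs + 1):n_pops
    pop_cells[rest] <- cell_ids[k:(k + length(rest) - 1)]
  }
  lineage <- sample(rep_len(seq_len(n_lineages), n_pops))
  out <- data.frame(pop_id = sprintf("P%02d", seq_len(n_pops)),
                    cell_id = pop_cells,
                    n_individuals = rep_len(n_individuals, n_pops),
                    ecotype = eco,
                    lineage = sprintf("L%d", lineage),
                    fst = rep_len(fst, n_pops),
                    lineage_fst = lineage_fst)
  class(out) <- c("population_design", "data.frame")
  out
}

## standardized value of one grid variable at the design's cells
standardized_causal <- function(design, grid, variable) {
  env <- design_env_table(design, grid)
  v <- env$values[, variable]
  s <- stats::sd(v)
  if (s == 0) return(rep(0, length(v)))
  (v - mean(v)) / s
}

#' Simulate dosage genotypes with planted adaptive loci
#'
#' Neutral loci follow the Balding-Nichols F-model: an ancestral frequency
#' `p ~ Uniform(maf_range)` and population frequencies
#' `q_k ~ Beta(p(1-F)/F, (1-p)(1-F)/F)`. Adaptive loci track climate:
#' `q_k = logistic(a + b z_k)` where `z_k` is the standardized causal
#' variable at population k's cell, `a = logit(p)` and
#' `|b| ~ Uniform(slope_range)` with random sign. Individual dosages are
#' `Binomial(2, q_k)` draws, masked missing independently at
#' `missing_rate`. The returned truth table records each locus's class,
#' causal variable, intercept and slope for recovery tests.
#'
#' @param design a [population_design()].
#' @param grid the [make_landscape()] grid the design lives on.
#' @param n_neutral,n_adaptive locus counts.
#' @param slope_range range of |b| on the standardized scale.
#' @param maf_range range of ancestral allele frequencies.
#' @param missing_rate independent missing-genotype probability in [0, 1).
#' @param causal_variables variables adaptive loci may track (default:
#'   all grid variables).
#' @param seed integer seed.
#' @param classes variant classes to tag loci with (default `"SNP"`).
#' @param chrom_loci loci per chromosome block (positions are spaced
#'   250 kb so default LD windows never span two simulated loci).
#' @return list with `genotypes` (a [genotype_matrix()]) and `truth`
#'   (data frame `locus_id`, `class`, `causal_variable`, `slope`,
#'   `intercept`).
#' @export
simulate_genotypes <- function(design, grid, n_neutral = 2000,
                               n_adaptive = 50, slope_range = c(2, 3),
                               maf_range = c(0.1, 0.5),
                               missing_rate = 0.02,
                               causal_variables = grid$variables,
                               seed = 1, classes = "SNP",
                               chrom_loci = 500) {
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must lie in [0, 1)")
  if (any(design$fst <= 0 | design$fst >= 1)) stop("fst must lie in (0, 1)")
  set.seed(seed)
  n_loci <- n_neutral + n_adaptive
  K <- nrow(design)
  n_ind <- sum(design$n_individuals)

  z <- vapply(causal_variables, function(v)
    standardized_causal(design, grid, v), numeric(K))
  z <- matrix(z, nrow = K, dimnames = list(design$pop_id, causal_variables))

  is_adaptive <- c(rep(FALSE, n_neutral), rep(TRUE, n_adaptive))
  is_adaptive <- is_adaptive[sample.int(n_loci)]
  p0 <- stats::runif(n_loci, maf_range[1], maf_range[2])
  slope <- ifelse(is_adaptive,
                  sample(c(-1, 1), n_loci, replace = TRUE) *
                    stats::runif(n_loci, slope_range[1], slope_range[2]),
                  0)
  causal <- ifelse(is_adaptive,
                   sample(causal_variables, n_loci, replace = TRUE),
                   NA_character_)
  intercept <- stats::qlogis(p0)

  # population frequencies: K x n_loci. Neutral loci drift hierarchically
  # (lineage around ancestral, population around lineage) so the leading
  # genotype PCs reflect shared history rather than the planted climate
  # axis; adaptive frequencies follow the logistic link exactly.
  lineages <- if ("lineage" %in% names(design)) design$lineage
              else rep("L1", K)
  lineage_fst <- if ("lineage_fst" %in% names(design)) design$lineage_fst[1]
                 else 1e-6
  lin_levels <- unique(lineages)
  lin_of <- match(lineages, lin_levels)
  bn_draw <- function(n, p, F) {
    p <- pmin(pmax(p, 1e-6), 1 - 1e-6)
    stats::rbeta(n, p * (1 - F) / F, (1 - p) * (1 - F) / F)
  }
  q <- matrix(NA_real_, K, n_loci)
  for (l in seq_len(n_loci)) {
    if (is_adaptive[l]) {
      q[, l] <- stats::plogis(intercept[l] + slope[l] * z[, causal[l]])
    } else {
      p_lin <- if (lineage_fst > 1e-6)
        bn_draw(length(lin_levels), p0[l], lineage_fst)
      else rep(p0[l], length(lin_levels))
      q[, l] <- bn_draw(K, p_lin[lin_of], design$fst)
    }
  }

  pop_of <- rep(seq_len(K), design$n_individuals)
  dosage <- matrix(stats::rbinom(n_ind * n_loci, 2, q[pop_of, ]),
                   n_ind, n_loci)
  if (missing_rate > 0)
    dosage[stats::runif(n_ind * n_loci) < missing_rate] <- NA

  ind_ids <- unlist(lapply(seq_len(K), function(k)
    sprintf("%s_i%02d", design$pop_id[k], seq_len(design$n_individuals[k]))))
  individuals <- data.frame(id = ind_ids,
                            population = design$pop_id[pop_of],
                            ecotype = design$ecotype[pop_of])

  chrom <- paste0("chr", (seq_len(n_loci) - 1) %/% chrom_loci + 1)
  pos <- ((seq_len(n_loci) - 1) %% chrom_loci) * 250000 + 1
  loc_class <- if (length(classes) == 1) rep(classes, n_loci)
               else sample(classes, n_loci, replace = TRUE)
  prefix <- if (identical(classes, "SNP")) "snp" else "sv"
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_loci, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  loci <- data.frame(id = sprintf("%s%05d", prefix, seq_len(n_loci)),
                     chrom = chrom, pos = pos, ref = ref, alt = alt,
                     class = loc_class)
  if (!identical(classes, "SNP")) {
    loci$ref <- "N"
    loci$alt <- paste0("<", loc_class, ">")
  }

  truth <- data.frame(
    locus_id = loci$id,
    class = ifelse(is_adaptive, "adaptive", "neutral"),
    causal_variable = causal,
    slope = slope,
    intercept = ifelse(is_adaptive, intercept, stats::qlogis(p0)))

  gm <- genotype_matrix(dosage, individuals, loci)
  list(genotypes = gm, truth = truth)
}

#' Simulate a structural-variant genotype panel
#'
#' Same generative model as [simulate_genotypes()] but loci are tagged
#' with SV classes (`DEL`, `DUP`, `INS`, `INV`), the default missingness
#' is higher (SV genotyping is noisier than SNP calling), and each
#' genotype carries a simulated paired-end read-support count in the
#' `SR` matrix, so support-based recoding can be exercised downstream.
#'
#' @inheritParams simulate_genotypes
#' @param n_loci total loci in the panel.
#' @param prop_adaptive fraction of loci made adaptive.
#' @param support_lambda Poisson mean of simulated read support.
#' @return list with `genotypes` and `truth` as in [simulate_genotypes()].
#' @export
simulate_sv_panel <- function(design, grid, n_loci = 500,
                              prop_adaptive = 0.05,
                              missing_rate = 0.10,
                              slope_range = c(2, 3),
                              maf_range = c(0.1, 0.5),
                              causal_variables = grid$variables,
                              support_lambda = 8, seed = 1) {
  n_adaptive <- round(n_loci * prop_adaptive)
  sim <- simulate_genotypes(design, grid,
                            n_neutral = n_loci - n_adaptive,
                            n_adaptive = n_adaptive,
                            slope_range = slope_range,
                            maf_range = maf_range,
                            missing_rate = missing_rate,
                            causal_variables = causal_variables,
                            seed = seed,
                            classes = c("DEL", "DUP", "INS", "INV"),
                            chrom_loci = 250)
  gm <- sim$genotypes
  support <- matrix(stats::rpois(length(gm$dosage), support_lambda),
                    nrow(gm$dosage), ncol(gm$dosage))
  support[is.na(gm$dosage)] <- 0L
  gm$support <- support
  rownames(gm$support) <- gm$individuals$id
  colnames(gm$support) <- gm$loci$id
  list(genotypes = gm, truth = sim$truth)
}

## dosage -> diploid GT string
dosage_to_gt <- function(d) {
  gt <- c("0/0", "0/1", "1/1")[d + 1]
  gt[is.na(d)] <- "./."
  gt
}

## write a genotype_matrix as a minimal VCF 4.2 file
write_vcf <- function(gm, path, support_field = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=landgea_synthetic",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Type of structural variant\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position of the variant\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=SR,Number=1,Type=Integer,Description=\"Supporting read pairs\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$individuals$id), collapse = "\t")
  ), con)
  is_sv <- gm$loci$class != "SNP"
  info <- ifelse(is_sv,
                 paste0("SVTYPE=", gm$loci$class, ";END=", gm$loci$pos + 100),
                 ".")
  fmt <- if (!is.null(support_field) && !is.null(gm$support))
    paste0("GT:", support_field) else "GT"
  for (j in seq_len(ncol(gm$dosage))) {
    gt <- dosage_to_gt(gm$dosage[, j])
    if (fmt != "GT") gt <- paste(gt, gm$support[, j], sep = ":")
    writeLines(paste(c(gm$loci$chrom[j], gm$loci$pos[j], gm$loci$id[j],
                       gm$loci$ref[j], gm$loci$alt[j], ".", "PASS",
                       info[j], fmt, gt), collapse = "\t"), con)
  }
  invisible(path)
}

#' Write a complete synthetic fixture to disk
#'
#' Emits a file set that round-trips losslessly through the package's
#' readers: SNP and SV VCFs (the SV VCF carries `INFO/SVTYPE` and a
#' per-genotype `SR` support field), wide recent/future environmental
#' CSVs at the population level, a long-format grid CSV, an individual
#' and a population table, the truth tables, and a JSON metadata record
#' of the seeds used.
#'
#' @param dir output directory (created if needed).
#' @param grid an [make_landscape()] grid.
#' @param design a [population_design()].
#' @param snps,svs simulation results from [simulate_genotypes()] /
#'   [simulate_sv_panel()] (lists with `genotypes` and `truth`).
#' @return named character vector of file paths, invisibly.
#' @export
write_fixture <- function(dir, grid, design, snps, svs = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    snp_vcf = file.path(dir, "snps.vcf"),
    env_recent = file.path(dir, "env_recent.csv"),
    populations = file.path(dir, "populations.csv"),
    individuals = file.path(dir, "individuals.csv"),
    grid = file.path(dir, "grid_long.csv"),
    snp_truth = file.path(dir, "truth_snps.csv"),
    meta = file.path(dir, "metadata.json"))
  write_vcf(snps$genotypes, paths["snp_vcf"])
  utils::write.csv(snps$truth, paths["snp_truth"], row.names = FALSE)
  if (!is.null(svs)) {
    paths["sv_vcf"] <- file.path(dir, "svs.vcf")
    paths["sv_truth"] <- file.path(dir, "truth_svs.csv")
    write_vcf(svs$genotypes, paths["sv_vcf"], support_field = "SR")
    utils::write.csv(svs$truth, paths["sv_truth"], row.names = FALSE)
  }
  write_env(design_env_table(design, grid, "recent"), paths["env_recent"])
  for (sc in names(grid$future)) {
    p <- file.path(dir, paste0("env_future_", sc, ".csv"))
    paths[paste0("env_future_", sc)] <- p
    write_env(design_env_table(design, grid, sc), p)
  }
  utils::write.csv(as.data.frame(design), paths["populations"],
                   row.names = FALSE)
  utils::write.csv(snps$genotypes$individuals, paths["individuals"],
                   row.names = FALSE)
  long <- do.call(rbind, c(
    list(data.frame(cell = grid$cells$cell_id, x = grid$cells$x,
                    y = grid$cells$y,
                    variable = rep(grid$variables, each = nrow(grid$cells)),
                    layer = "recent",
                    value = as.vector(grid$recent))),
    lapply(names(grid$future), function(sc)
      data.frame(cell = grid$cells$cell_id, x = grid$cells$x,
                 y = grid$cells$y,
                 variable = rep(grid$variables, each = nrow(grid$cells)),
                 layer = sc, value = as.vector(grid$future[[sc]])))))
  utils::write.csv(long, paths["grid"], row.names = FALSE)
  jsonlite::write_json(list(grid_seed = grid$seed,
                            n_populations = nrow(design),
                            scenarios = names(grid$future)),
                       paths["meta"], auto_unbox = TRUE)
  invisible(paths)
}
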
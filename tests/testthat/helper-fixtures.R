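# Shared fixtures, computed once per test run and cached. The default
# fixture is the package's canonical study-scale dataset (20 populations x
# 10 individuals, 2,000 neutral + 50 adaptive SNPs tracking bio5).

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

get_fixture <- function() cached("fixture", default_fixture(seed = 1))

get_site_env <- function() {
  fx <- get_fixture()
  cached("site_env", design_env_table(fx$design, fx$grid))
}

get_gea <- function() {
  fx <- get_fixture()
  cached("gea", run_gea(fx$snps$genotypes, standardize_env(get_site_env())))
}

get_gf <- function() {
  cached("gf", {
    fx <- get_fixture()
    res <- get_gea()
    strong_gm <- landgea:::subset_gm(
      fx$snps$genotypes,
      loc_keep = fx$snps$genotypes$loci$id %in% res$strong$locus_id)
    freqs <- allele_frequencies(strong_gm)
    env <- get_site_env()
    fit_gradient_forest(freqs, env$values[freqs$groups, , drop = FALSE],
                        n_trees = 500, seed = 11)
  })
}

climate_vars <- c("bio5", "bio6", "bio15", "bio16")

get_adaptive_fit <- function() {
  cached("adaptive_fit", {
    res <- get_gea()
    env_std <- standardize_env(get_site_env())
    env4 <- env_table(env_std$values[, climate_vars],
                      ids = env_std$ids,
                      standardization = lapply(env_std$standardization,
                                               function(p) p[climate_vars]))
    adaptive_enriched_rda(res$gm_imputed, res$strong, env4, res$pcs)
  })
}

get_std_grid <- function(layer = "recent") {
  fx <- get_fixture()
  site_env <- get_site_env()
  ref <- env_table(site_env$values[, climate_vars], ids = site_env$ids)
  grid_tab <- grid_env_table(fx$grid, layer)
  std <- standardize_env(
    env_table(grid_tab$values[, climate_vars], ids = grid_tab$ids,
              layer = grid_tab$layer),
    reference = ref)
  attr(std, "coords") <- attr(grid_tab, "coords")
  std
}

# tiny genotype matrix from explicit dosages (individuals x loci)
toy_gm <- function(dosage, chrom = NULL, pos = NULL, class = "SNP",
                   population = NULL, support = NULL) {
  n <- nrow(dosage); m <- ncol(dosage)
  genotype_matrix(
    dosage,
    individuals = data.frame(id = sprintf("i%02d", seq_len(n)),
                             population = population %||% rep("P1", n)),
    loci = data.frame(id = sprintf("L%03d", seq_len(m)),
                      chrom = chrom %||% rep("chr1", m),
                      pos = pos %||% seq_len(m),
                      ref = rep("A", m), alt = rep("T", m),
                      class = rep_len(class, m)),
    support = support)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
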
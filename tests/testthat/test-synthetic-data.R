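test_that("future layers are additive over the recent layer", {
  grid <- make_landscape(10, 10,
    gradients = list(bio5 = list(direction = "y", range = c(20, 35))),
    deltas = list(bio5 = list(rcp85 = 5, flat = 0)), seed = 3)
  expect_equal(grid$future$rcp85[, "bio5"], grid$recent[, "bio5"] + 5)
  expect_identical(grid$future$flat, grid$recent)
})

test_that("landscape and genotype generation are deterministic under a seed", {
  g1 <- make_landscape(6, 6, gradients = default_gradients(),
                       deltas = default_deltas(), noise_sd = 1, seed = 42)
  g2 <- make_landscape(6, 6, gradients = default_gradients(),
                       deltas = default_deltas(), noise_sd = 1, seed = 42)
  expect_identical(g1, g2)

  des <- population_design(g1, n_pops = 6, n_individuals = 4, seed = 9)
  s1 <- simulate_genotypes(des, g1, 50, 5, seed = 13)
  s2 <- simulate_genotypes(des, g1, 50, 5, seed = 13)
  expect_identical(s1$genotypes$dosage, s2$genotypes$dosage)
  expect_identical(s1$truth, s2$truth)
})

test_that("configuration errors are raised for bad specs", {
  expect_error(make_landscape(1, 2, gradients = default_gradients()),
               "at least 4")
  expect_error(
    make_landscape(5, 5,
                   gradients = list(bio5 = list(direction = "y",
                                                range = c(0, 1))),
                   deltas = list(bogus = list(rcp85 = 1))),
    "unknown variable")
  grid <- make_landscape(5, 5, gradients = default_gradients(), seed = 1)
  expect_error(population_design(grid, 5, 4, fst = 1.2), "fst")
})

test_that("neutral population frequencies stay near ancestral at small F", {
  # with F -> 0 the Balding-Nichols variance p(1-p)F vanishes; observed
  # population frequencies (300 individuals/pop) approximate q closely
  grid <- make_landscape(4, 4, gradients = default_gradients(), seed = 5)
  des <- population_design(grid, n_pops = 3, n_individuals = 300,
                           fst = 0.001, n_lineages = 1, lineage_fst = 0,
                           seed = 5)
  sim <- simulate_genotypes(des, grid, n_neutral = 1000, n_adaptive = 0,
                            missing_rate = 0, seed = 5)
  freqs <- allele_frequencies(sim$genotypes)
  p0 <- stats::plogis(sim$truth$intercept)
  dev <- abs(sweep(freqs$freq, 2, p0))
  expect_lt(mean(dev), 0.05)
})

test_that("missingness mask hits its nominal rate", {
  grid <- make_landscape(4, 4, gradients = default_gradients(), seed = 2)
  des <- population_design(grid, n_pops = 10, n_individuals = 10, seed = 2)
  sim <- simulate_genotypes(des, grid, n_neutral = 100, n_adaptive = 0,
                            missing_rate = 0.1, seed = 2)
  expect_equal(mean(is.na(sim$genotypes$dosage)), 0.1, tolerance = 0.2)
  expect_lt(abs(mean(is.na(sim$genotypes$dosage)) - 0.1), 0.02)
})

test_that("planted adaptive loci track their causal variable across populations", {
  # |b| >= 2 on the standardized scale, small F, 20 populations: the
  # frequency-environment correlation should exceed 0.6 for >= 90% of loci
  fx <- get_fixture()
  freqs <- allele_frequencies(fx$snps$genotypes)
  env <- get_site_env()
  z <- scale(env$values[freqs$groups, "bio5"])
  ad <- fx$snps$truth$locus_id[fx$snps$truth$class == "adaptive"]
  r <- abs(cor(freqs$freq[, ad], z, use = "pairwise.complete.obs"))
  expect_gte(mean(r > 0.6), 0.9)
})

test_that("b = 0 reduces the adaptive model to a constant-frequency locus", {
  grid <- make_landscape(4, 4, gradients = default_gradients(), seed = 8)
  des <- population_design(grid, n_pops = 8, n_individuals = 20, seed = 8)
  sim <- simulate_genotypes(des, grid, n_neutral = 0, n_adaptive = 30,
                            slope_range = c(0, 0), missing_rate = 0, seed = 8)
  freqs <- allele_frequencies(sim$genotypes)
  p0 <- stats::plogis(sim$truth$intercept)
  # every population's frequency is a Binomial(2n, p0) estimate of the same p0
  expect_lt(max(abs(sweep(freqs$freq, 2, p0))), 0.25)
  expect_true(all(sim$truth$slope == 0))
})

test_that("SV panel carries SV classes, support counts and higher missingness", {
  fx <- get_fixture()
  sv <- fx$svs$genotypes
  expect_equal(n_loci(sv), 500)
  expect_true(all(sv$loci$class %in% c("DEL", "DUP", "INS", "INV")))
  expect_false(is.null(sv$support))
  site_miss <- colMeans(is.na(sv$dosage))
  expect_equal(mean(site_miss), 0.10, tolerance = 0.02)
  sv2 <- simulate_sv_panel(fx$design, fx$grid, n_loci = 500,
                           missing_rate = 0.10,
                           causal_variables = "bio5", seed = 4)
  sv2b <- simulate_sv_panel(fx$design, fx$grid, n_loci = 500,
                            missing_rate = 0.10,
                            causal_variables = "bio5", seed = 4)
  expect_identical(sv2$genotypes$dosage, sv2b$genotypes$dosage)
})

test_that("fixture files round-trip losslessly through the readers", {
  fx <- get_fixture()
  dir <- withr::local_tempdir()
  paths <- write_fixture(dir, fx$grid, fx$design, fx$snps, fx$svs)

  gm <- read_vcf(paths[["snp_vcf"]])
  expect_equal(unname(gm$dosage), unname(fx$snps$genotypes$dosage))
  sv <- read_vcf(paths[["sv_vcf"]], support_field = "SR")
  expect_equal(unname(sv$dosage), unname(fx$svs$genotypes$dosage))
  expect_equal(unname(sv$support) * 1.0,
               unname(fx$svs$genotypes$support) * 1.0)
  expect_true(all(grepl("SVTYPE=", grep("^[^#]", readLines(paths[["sv_vcf"]]),
                                        value = TRUE))))

  truth <- read.csv(paths[["snp_truth"]])
  expect_equal(nrow(truth), 2050)

  env <- load_env(paths[["env_recent"]])
  expect_equal(unname(env$values),
               unname(design_env_table(fx$design, fx$grid)$values))
  grid_layers <- load_env_grid(paths[["grid"]])
  expect_setequal(names(grid_layers), c("recent", "rcp26", "rcp85"))
  expect_equal(unname(grid_layers$recent$values[, fx$grid$variables]),
               unname(fx$grid$recent))
})

test_that("study-scale fixture generation is fast", {
  t0 <- Sys.time()
  fx <- default_fixture(seed = 99, n_sv = 100)
  expect_lt(as.numeric(difftime(Sys.time(), t0, units = "secs")), 30)
  expect_equal(dim(fx$snps$genotypes), c(200L, 2050L))
})

test_that("dosages and frequencies respect their domains", {
  fx <- get_fixture()
  d <- fx$snps$genotypes$dosage
  expect_true(all(d[!is.na(d)] %in% 0:2))
  freqs <- allele_frequencies(fx$snps$genotypes)
  f <- freqs$freq[!is.na(freqs$freq)]
  expect_true(all(f >= 0 & f <= 1))
})
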
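# exhaustive single-tree CART oracle for tiny inputs: one predictor,
# best variance-reducing split with children of at least min_node points
cart_oracle_splits <- function(x, y, min_node = 2) {
  n <- length(y)
  recurse <- function(idx) {
    if (length(idx) < 2 * min_node || var(y[idx]) == 0) return(NULL)
    xs <- x[idx]; ys <- y[idx]
    cands <- sort(unique(xs))
    best <- NULL
    for (c_i in cands[-length(cands)]) {
      left <- xs <= c_i
      if (sum(left) < min_node || sum(!left) < min_node) next
      dec <- sum((ys - mean(ys))^2) -
        sum((ys[left] - mean(ys[left]))^2) -
        sum((ys[!left] - mean(ys[!left]))^2)
      mid <- (c_i + min(xs[xs > c_i])) / 2
      if (is.null(best) || dec > best$dec) best <- list(val = mid, dec = dec)
    }
    if (is.null(best) || best$dec <= 0) return(NULL)
    rbind(data.frame(value = best$val, decrease = best$dec),
          recurse(idx[xs <= best$val]), recurse(idx[xs > best$val]))
  }
  recurse(seq_len(n))
}

test_that("a single tree's masses are its split records, hand-traceable", {
  x <- matrix(c(1, 2, 3, 4, 5, 6, 7, 8), ncol = 1,
              dimnames = list(NULL, "bio5"))
  y <- c(0.1, 0.12, 0.1, 0.45, 0.5, 0.48, 0.9, 0.92)
  model <- fit_gradient_forest(matrix(y, ncol = 1,
                                      dimnames = list(NULL, "L1")),
                               x, n_trees = 1, bootstrap = FALSE,
                               mtry = 1, seed = 5)
  oracle <- cart_oracle_splits(x[, 1], y)
  s <- model$splits$bio5
  expect_setequal(s$value, oracle$value)
  # masses are the decreases rescaled to sum to the locus R2
  r2 <- unname(model$locus_r2["L1"])
  oracle_mass <- oracle$decrease / sum(oracle$decrease) * r2
  expect_equal(s$mass[match(oracle$value, s$value)], oracle_mass,
               tolerance = 1e-12)
  expect_equal(sum(s$mass), unname(model$importance["bio5"]),
               tolerance = 1e-12)
})

test_that("turnover is a monotone step function from 0 to total importance", {
  gf <- get_gf()
  for (p in gf$predictors) {
    s <- gf$splits[[p]]
    if (!nrow(s)) next
    lo <- min(s$value) - 1; hi <- max(s$value) + 1
    expect_equal(turnover(gf, p, lo), 0)
    expect_equal(turnover(gf, p, hi), unname(gf$importance[p]),
                 tolerance = 1e-12)
    grid <- seq(lo, hi, length.out = 101)
    expect_true(all(diff(turnover(gf, p, grid)) >= 0))
    expect_true(all(s$mass >= 0))
  }
  expect_error(turnover(gf, "nope", 1), "unknown predictor")
})

test_that("the causal predictor ranks first in R2-weighted importance", {
  gf <- get_gf()
  expect_equal(names(which.max(gf$importance)), "bio5")
  expect_true(all(gf$locus_r2 > 0))
})

test_that("pure-noise responses carry no importance", {
  # at a site count where out-of-bag R2 is stable, iid-uniform responses
  # are either all discarded or contribute a trickle of importance
  # relative to an equally sized planted-signal panel
  set.seed(51)
  env <- matrix(rnorm(60 * 4), 60, 4, dimnames = list(NULL, paste0("v", 1:4)))
  noise <- matrix(runif(60 * 30), 60, 30,
                  dimnames = list(NULL, paste0("N", 1:30)))
  res <- tryCatch(fit_gradient_forest(noise, env, n_trees = 200, seed = 51),
                  error = function(e) e)
  y <- plogis(2 * scale(env[, 1])[, 1] + rnorm(60, sd = 0.3))
  sig <- fit_gradient_forest(
    matrix(rep(y, 5) + rnorm(300, sd = 0.05), 60, 5,
           dimnames = list(NULL, paste0("S", 1:5))),
    env, n_trees = 200, seed = 52)
  expect_equal(names(which.max(sig$importance)), "v1")
  if (inherits(res, "error")) {
    expect_match(conditionMessage(res), "no signal")
  } else {
    expect_lt(max(res$importance), 0.05 * max(sig$importance))
  }
})

test_that("offset is zero under identical layers and equals total mass across the range", {
  gf <- get_gf()
  env <- get_site_env()
  off0 <- genomic_offset(gf, env, env, predictors = "bio5")
  expect_true(all(off0$offset == 0))
  # from below every split to above every split: offset = total bio5 mass
  s <- gf$splits$bio5
  cur <- matrix(min(s$value) - 10, 3, 1, dimnames = list(letters[1:3], "bio5"))
  fut <- matrix(max(s$value) + 10, 3, 1, dimnames = list(letters[1:3], "bio5"))
  off <- genomic_offset(gf, cur, fut, predictors = "bio5")
  expect_equal(off$offset, rep(unname(gf$importance["bio5"]), 3),
               tolerance = 1e-12)
  expect_error(genomic_offset(gf, cur, fut, predictors = "bogus"),
               "not fitted")
})

test_that("offset behaves as a metric in turnover space", {
  gf <- get_gf()
  fx <- get_fixture()
  a <- grid_env_table(fx$grid, "recent")
  b <- grid_env_table(fx$grid, "rcp26")
  c3 <- grid_env_table(fx$grid, "rcp85")
  d_ab <- genomic_offset(gf, a, b, "bio5")$offset
  d_ba <- genomic_offset(gf, b, a, "bio5")$offset
  expect_equal(d_ab, d_ba)
  d_ac <- genomic_offset(gf, a, c3, "bio5")$offset
  d_bc <- genomic_offset(gf, b, c3, "bio5")$offset
  expect_true(all(d_ac <= d_ab + d_bc + 1e-12))
})

test_that("offset responds monotonically to the magnitude of warming", {
  gf <- get_gf()
  fx <- get_fixture()
  cur <- grid_env_table(fx$grid, "recent")
  fut <- grid_env_table(fx$grid, "rcp85")
  delta <- fut$values[, "bio5"] - cur$values[, "bio5"]
  base <- matrix(colMeans(cur$values), nrow(cur$values), ncol(cur$values),
                 byrow = TRUE, dimnames = dimnames(cur$values))
  futb <- base; futb[, "bio5"] <- base[, "bio5"] + delta
  off <- genomic_offset(gf, base, futb, predictors = "bio5")
  expect_gt(cor(off$offset, abs(delta), method = "spearman"), 0.9)
})

test_that("SNP- and SV-based offsets agree when driven by the same variable", {
  fx <- get_fixture()
  gf_snp <- get_gf()
  env <- get_site_env()
  # strong SV candidates straight from the simulator's truth table
  sv_ad <- fx$svs$truth$locus_id[fx$svs$truth$class == "adaptive"]
  sv_gm <- landgea:::subset_gm(fx$svs$genotypes,
                               loc_keep = fx$svs$genotypes$loci$id %in% sv_ad)
  freqs <- allele_frequencies(sv_gm)
  gf_sv <- fit_gradient_forest(freqs, env$values[freqs$groups, ],
                               n_trees = 200, seed = 52)
  cur <- grid_env_table(fx$grid, "recent")
  fut <- grid_env_table(fx$grid, "rcp85")
  o_snp <- genomic_offset(gf_snp, cur, fut, "bio5")$offset
  o_sv <- genomic_offset(gf_sv, cur, fut, "bio5")$offset
  expect_gt(cor(o_snp, o_sv, method = "spearman"), 0)
})

test_that("fits are deterministic under a fixed seed", {
  env <- get_site_env()
  set.seed(99)  # outside noise must not leak in
  y <- matrix(plogis(scale(env$values[, "bio5"]) * 2 + rnorm(20, sd = 0.2)),
              ncol = 1, dimnames = list(env$ids, "L1"))
  m1 <- fit_gradient_forest(y, env$values, n_trees = 50, seed = 7)
  m2 <- fit_gradient_forest(y, env$values, n_trees = 50, seed = 7)
  expect_identical(m1$splits, m2$splits)
  expect_identical(m1$importance, m2$importance)
})

test_that("ecotype groups are split, matched and scored per group", {
  fx <- get_fixture()
  res <- get_gea()
  env <- get_site_env()
  fut <- design_env_table(fx$design, fx$grid, "rcp85")
  off <- ecotype_offsets(fx$snps$genotypes, res$strong$locus_id,
                         env, fut, n_trees = 100, seed = 9)
  expect_true(all(is.finite(off$offset)))
  expect_true(all(off$offset >= 0))
  # co-occurring pairs produce one row per ecotype, others one "all" row
  paired <- fx$design$pop_id[fx$design$ecotype %in% c("stream", "shore")]
  expect_setequal(off$ecotype[off$population %in% paired],
                  c("stream", "shore"))
  expect_true(all(off$ecotype[!off$population %in% paired] == "all"))
  # identical ecotype genotypes produce identical offsets
  pat <- cbind(c(0, 1, 2, 0, 1, 2),
               c(2, 2, 0, 1, 0, 1),
               c(0, 0, 1, 1, 2, 2),
               c(1, 2, 0, 2, 0, 1))
  d <- pat[rep(1:6, each = 2), ]
  gm <- genotype_matrix(
    d,
    individuals = data.frame(id = sprintf("i%02d", 1:12),
                             population = rep(paste0("P", 1:6), each = 2),
                             ecotype = rep(c("stream", "shore"), 6)),
    loci = data.frame(id = paste0("L", 1:4), chrom = "chr1", pos = 1:4,
                      ref = "A", alt = "T", class = "SNP"))
  env_toy <- env_table(matrix(1:6, 6, 1, dimnames = list(NULL, "bio5")),
                       ids = paste0("P", 1:6))
  fut_toy <- env_table(matrix(1:6 + 2, 6, 1, dimnames = list(NULL, "bio5")),
                       ids = paste0("P", 1:6))
  off_toy <- ecotype_offsets(gm, paste0("L", 1:4), env_toy, fut_toy,
                             n_trees = 30, seed = 10)
  for (p in paste0("P", 1:6)) {
    vals <- off_toy$offset[off_toy$population == p]
    expect_equal(vals[1], vals[2])
  }
})
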
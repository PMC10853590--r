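write_mini_vcf <- function(lines) {
  path <- withr::local_tempfile(fileext = ".vcf",
                                .local_envir = parent.frame())
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=SR,Number=1,Type=Integer,Description=\"Support\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2",
    lines), path)
  path
}

test_that("GT strings map to dosages, phased and missing included", {
  path <- write_mini_vcf(c(
    "chr1\t100\tv1\tA\tT\t.\tPASS\t.\tGT\t0/1\t1/1",
    "chr1\t200\tv2\tA\tT\t.\tPASS\t.\tGT\t./.\t1|0",
    "chr1\t300\tv3\tA\tT,G\t.\tPASS\t.\tGT\t0/0\t0/1",
    "chr1\t400\tv4\tAC\tA\t.\tPASS\t.\tGT\t0/0\t1/1"))
  gm <- read_vcf(path)
  expect_equal(unname(gm$dosage[, "v1"]), c(1, 2))
  expect_equal(unname(gm$dosage[, "v2"]), c(NA, 1))
  expect_false(gm$loci$biallelic[3])   # multi-allelic flagged
  expect_true(gm$loci$is_indel[4])
})

test_that("non-diploid genotypes are rejected", {
  path <- write_mini_vcf("chr1\t100\tv1\tA\tT\t.\tPASS\t.\tGT\t0/1/1\t0/0")
  expect_error(read_vcf(path), "diploid")
})

test_that("site filter drops multi-allelics, indels and missing-heavy loci", {
  # 10 loci with missing fractions 0, 0.1, ..., 0.9 over 10 individuals:
  # survivors under the 0.30 ceiling are exactly those below it
  d <- sapply(0:9, function(k) c(rep(NA, k), rep(1, 10 - k)))
  gm <- toy_gm(d)
  out <- filter_sites(gm, max_site_missing = 0.30)
  miss <- colMeans(is.na(d))
  expect_equal(out$loci$id, gm$loci$id[miss < 0.30])  # brute-force oracle
  expect_equal(n_loci(out), 3)
  # boundary: exactly 30% missing is removed ("less than 30%" retained)
  d2 <- cbind(c(NA, NA, NA, rep(0, 7)), rep(1, 10))
  out2 <- filter_sites(toy_gm(d2), max_site_missing = 0.30)
  expect_equal(n_loci(out2), 1)
})

test_that("individual filter uses a strict > threshold", {
  # 5 individuals x 10 loci with per-individual missingness 0 to 0.4
  set.seed(2)
  d <- matrix(sample(0:2, 50, replace = TRUE), 5, 10)
  for (k in 1:4) d[k + 1, seq_len(k)] <- NA
  gm <- toy_gm(d)
  out <- filter_individuals(gm, max_ind_missing = 0.30)
  keep_oracle <- rowMeans(is.na(d)) <= 0.30
  expect_equal(out$individuals$id, gm$individuals$id[keep_oracle])
  expect_equal(n_individuals(out), 4)  # 0.4 missing removed, 0.3 retained
})

test_that("low-support genotypes are recoded missing, boundary inclusive", {
  d <- matrix(c(0, 1, 2, 1), 2, 2)
  sup <- matrix(c(2, 3, 10, 4), 2, 2)
  gm <- toy_gm(d, support = sup)
  out <- recode_low_support(gm, min_support = 3)
  expect_true(is.na(out$dosage[1, 1]))       # support 2 -> missing
  expect_equal(out$dosage[2, 1], 1)          # support 3 unchanged
  gm_ok <- toy_gm(d, support = matrix(5, 2, 2))
  expect_identical(recode_low_support(gm_ok)$dosage, gm_ok$dosage)
  expect_error(recode_low_support(toy_gm(d)), "support")
})

test_that("LD pruning keeps one of two identical nearby loci", {
  set.seed(1)
  x <- sample(0:2, 40, replace = TRUE)
  gm <- toy_gm(cbind(x, x), pos = c(1000, 2000))
  expect_equal(n_loci(ld_prune(gm)), 1)
  # r^2 below the threshold: both retained
  y <- x; y[1:14] <- sample(0:2, 14, replace = TRUE)
  gm2 <- toy_gm(cbind(x, y), pos = c(1000, 2000))
  r2 <- cor(x, y)^2
  out2 <- ld_prune(gm2, r2_threshold = r2 + 0.01)
  expect_equal(n_loci(out2), 2)
})

test_that("LD pruning matches the all-pairs greedy oracle", {
  set.seed(7)
  n <- 30; m <- 50
  base <- matrix(sample(0:2, n * m, replace = TRUE), n, m)
  # inject correlated pairs at assorted distances
  for (j in seq(2, 40, by = 4)) {
    base[, j] <- base[, j - 1]
    flip <- sample(n, 3)
    base[flip, j] <- sample(0:2, 3, replace = TRUE)
  }
  pos <- sort(sample(1:600000, m))
  gm <- toy_gm(base, pos = pos)
  pruned <- ld_prune(gm, r2_threshold = 0.5, window_bp = 200000)
  expect_equal(pruned$loci$id, ld_prune_oracle(gm, 0.5, 200000))
  # idempotence
  expect_equal(ld_prune(pruned)$loci$id, pruned$loci$id)
  # unsorted input rejected
  gm_rev <- toy_gm(base[, m:1], pos = rev(pos))
  expect_error(ld_prune(gm_rev), "sorted")
})

test_that("BED exclusion converts 0-based half-open intervals correctly", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t99\t200", bed)
  gm <- toy_gm(matrix(0, 2, 3), pos = c(99, 100, 200))
  out <- exclude_regions(gm, bed)
  expect_equal(out$loci$pos, 99)   # 100 and 200 fall inside (99, 200]
  # randomized check against a direct interval comparison
  set.seed(3)
  pos <- sample(1:1000, 60)
  gm2 <- toy_gm(matrix(0, 2, 60), pos = sort(pos))
  iv <- cbind(start = c(10, 300, 700), end = c(120, 450, 950))
  bed2 <- withr::local_tempfile(fileext = ".bed")
  writeLines(paste("chr1", iv[, 1], iv[, 2], sep = "\t"), bed2)
  out2 <- exclude_regions(gm2, bed2)
  inside <- vapply(gm2$loci$pos, function(p)
    any(p >= iv[, 1] + 1 & p <= iv[, 2]), logical(1))
  expect_equal(out2$loci$id, gm2$loci$id[!inside])
})

test_that("mode imputation fills missing entries deterministically", {
  gm <- toy_gm(cbind(c(0, 0, 1, NA), c(0, 0, 1, 1), c(2, 2, NA, 1)))
  out <- impute_mode(gm)
  expect_equal(out$dosage[4, 1], 0)
  expect_equal(out$dosage[3, 3], 2)
  # tie between 0 and 1 -> smaller dosage
  gm_tie <- toy_gm(matrix(c(0, 0, 1, 1, NA), 5, 1))
  expect_equal(impute_mode(gm_tie)$dosage[5, 1], 0)
  # contract: no missing remains, observed entries untouched
  set.seed(4)
  d <- matrix(sample(c(0:2, NA), 200, replace = TRUE), 20, 10)
  d[, colSums(!is.na(d)) == 0] <- 0
  gm_r <- toy_gm(d)
  out_r <- impute_mode(gm_r)
  expect_false(anyNA(out_r$dosage))
  expect_equal(out_r$dosage[!is.na(d)], d[!is.na(d)])
  expect_error(impute_mode(toy_gm(matrix(NA_real_, 3, 1))), "impute")
})

test_that("allele frequencies are alt alleles over non-missing alleles", {
  gm <- toy_gm(matrix(c(0, 1, 2, NA, NA, NA), 3, 2),
               population = rep("P1", 3))
  f <- allele_frequencies(gm)
  expect_equal(unname(f$freq[1, 1]), 0.5)       # (0+1+2)/6
  expect_true(is.na(f$freq[1, 2]))              # all-missing cell
  # fixture populations: frequencies equal a direct recount
  fx <- get_fixture()
  gm_fx <- fx$snps$genotypes
  f_fx <- allele_frequencies(gm_fx)
  k <- "P07"; rows <- gm_fx$individuals$population == k
  manual <- colSums(gm_fx$dosage[rows, ], na.rm = TRUE) /
    (2 * colSums(!is.na(gm_fx$dosage[rows, ])))
  expect_equal(unname(f_fx$freq[k, ]), unname(manual))
})

test_that("filters are idempotent and their logs reconcile", {
  fx <- get_fixture()
  gm <- fx$snps$genotypes
  f1 <- filter_sites(gm)
  expect_identical(filter_sites(f1)$dosage, f1$dosage)
  f2 <- filter_individuals(f1)
  expect_identical(filter_individuals(f2)$dosage, f2$dosage)
  f3 <- ld_prune(f2)
  expect_identical(ld_prune(f3)$dosage, f3$dosage)
  for (rec in f3$log) {
    expect_gte(rec$removed, 0)
    expect_gte(rec$retained, 0)
  }
  # counts reconcile per locus-removing op
  expect_equal(f3$log[[1]]$removed + f3$log[[1]]$retained, n_loci(gm))
})
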
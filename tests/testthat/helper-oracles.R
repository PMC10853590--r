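# Independent oracles shared across test files. Each reimplements the
# checked computation from its definition via a different route than the
# package (explicit normal equations + eigen(); all-pairs greedy scans),
# so agreement is informative.

# regression-then-eigendecomposition RDA oracle
rda_oracle <- function(Y, X, Z = NULL) {
  Y <- scale(Y, scale = FALSE)
  X <- scale(X)
  if (!is.null(Z)) {
    Z1 <- cbind(1, Z)
    H <- Z1 %*% solve(crossprod(Z1)) %*% t(Z1)
    Y <- Y - H %*% Y
    X <- X - H %*% X
  }
  B <- solve(crossprod(X)) %*% crossprod(X, Y)
  Yhat <- X %*% B
  n <- nrow(Y)
  ev <- eigen(crossprod(Yhat) / (n - 1), symmetric = TRUE)
  k <- sum(ev$values > max(ev$values) * 1e-12)
  list(eigenvalues = ev$values[seq_len(k)],
       loadings = ev$vectors[, seq_len(k), drop = FALSE],
       r2 = sum(Yhat^2) / sum(Y^2))
}

# O(n^2) LD-pruning oracle: global greedy over co-windowed pairs, windows
# anchored at absolute multiples of half the window width
ld_prune_oracle <- function(gm, r2 = 0.5, w = 200000) {
  pos <- gm$loci$pos; chrom <- gm$loci$chrom
  m <- length(pos)
  co_windowed <- function(i, j) {
    if (chrom[i] != chrom[j]) return(FALSE)
    lo <- min(pos[i], pos[j]); hi <- max(pos[i], pos[j])
    ks <- seq(floor((hi - w) / (w / 2)), ceiling(lo / (w / 2)))
    any(ks * (w / 2) <= lo & hi < ks * (w / 2) + w)
  }
  removed <- rep(FALSE, m)
  for (j in seq_len(m)) {
    for (i in seq_len(j - 1)) {
      if (removed[i] || !co_windowed(i, j)) next
      r <- suppressWarnings(cor(gm$dosage[, i], gm$dosage[, j],
                                use = "pairwise.complete.obs"))
      if (!is.na(r) && r^2 > r2) { removed[j] <- TRUE; break }
    }
  }
  gm$loci$id[!removed]
}

# heterozygosity-environment data generator with known slope: the
# generating model is the oracle for mixed-model recovery/calibration
simulate_het_data <- function(slope, seed, n_pops = 20, n_ind = 10,
                              pop_sd = 0.01, noise_sd = 0.005) {
  set.seed(seed)
  z <- rnorm(n_pops)
  pop <- rep(sprintf("P%02d", seq_len(n_pops)), each = n_ind)
  u <- rnorm(n_pops, sd = pop_sd)
  het <- 0.4 + slope * z[rep(seq_len(n_pops), each = n_ind)] +
    u[rep(seq_len(n_pops), each = n_ind)] +
    rnorm(n_pops * n_ind, sd = noise_sd)
  list(het = data.frame(id = seq_along(het), population = pop,
                        ecotype = "none", proportion_heterozygous = het,
                        n_genotyped = 1000L),
       env = env_table(matrix(z, ncol = 1,
                              dimnames = list(NULL, "bio5")),
                       ids = sprintf("P%02d", seq_len(n_pops))))
}
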
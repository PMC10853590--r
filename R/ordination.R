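## Constrained and unconstrained ordination built directly on the SVD.
## Conventions: sample covariance divides by (n - 1); eigenvector signs are
## fixed so each axis's largest-magnitude loading entry is positive, making
## runs reproducible across BLAS implementations.

## deterministic sign fix applied to a loadings matrix and the paired scores
fix_signs <- function(loadings, ...) {
  flips <- apply(loadings, 2, function(v) {
    s <- sign(v[which.max(abs(v))])
    if (s == 0) 1 else s
  })
  out <- list(loadings = sweep(loadings, 2, flips, "*"))
  extra <- list(...)
  for (nm in names(extra))
    out[[nm]] <- sweep(extra[[nm]], 2, flips, "*")
  out$flips <- flips
  out
}

#' Principal component analysis of a genotype (or any) matrix
#'
#' Eigen-decomposition of the sample covariance via SVD of the centered
#' data. Scores are `centered data %*% loadings`; eigenvalues are the
#' per-axis variances; the proportion of variance per axis sums to 1 over
#' the full rank.
#'
#' @param X numeric matrix (samples x features); centered internally.
#' @param k number of components to retain.
#' @return object of class `pca_result`: `scores` (n x k), `loadings`
#'   (m x k), `eigenvalues`, `prop_var`, `center`.
#' @export
pca <- function(X, k = 3) {
  X <- as.matrix(X)
  n <- nrow(X); m <- ncol(X)
  if (k > min(n - 1, m))
    stop("k = ", k, " exceeds min(n - 1, m) = ", min(n - 1, m))
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  s <- svd(Xc, nu = k, nv = k)
  eig <- s$d^2 / (n - 1)
  fx <- fix_signs(s$v, scores = s$u %*% diag(s$d[seq_len(k)], k, k))
  structure(list(scores = fx$scores, loadings = fx$loadings,
                 eigenvalues = eig[seq_len(k)],
                 prop_var = eig[seq_len(k)] / sum(eig),
                 total_variance = sum(eig), center = ctr),
            class = "pca_result")
}

## residualize columns of M on [1, Z] by least squares; qr.fitted handles
## rank-deficient conditioning tables (redundant columns change nothing)
residualize <- function(M, Z) {
  if (is.null(Z)) return(scale(M, scale = FALSE))
  Z1 <- cbind(1, as.matrix(Z))
  M - qr.fitted(qr(Z1), M)
}

#' Redundancy analysis (RDA) and partial RDA
#'
#' Multivariate least squares of centered responses on standardized
#' predictors followed by eigen-decomposition of the fitted values'
#' covariance. When conditioning variables `Z` are given, both `Y` and
#' `X` are first replaced by their residuals from regression on `[1, Z]`
#' (partial RDA). `R2` is the ratio of constrained to total variance of
#' the (possibly residualized) responses; `adj_r2` applies the Ezekiel
#' correction `1 - (1 - R2)(n - 1)/(n - p - 1)`.
#'
#' Locus loadings are the responses' projections onto the constrained
#' axes; sample scores are given both as fitted-value ("lc") and observed
#' ("wa") projections; variable (biplot) scores are Pearson correlations
#' of each predictor with the fitted sample scores.
#'
#' @param Y response matrix (n x m), e.g. individual dosages; centered
#'   internally (optionally scaled with `scale_loci`).
#' @param X predictor table (n x p); standardized internally.
#' @param Z optional conditioning table (n x q).
#' @param scale_loci also scale response columns to unit variance.
#' @return object of class `rda_result` with `eigenvalues`, `loadings`
#'   (m x k), `scores` (lc, n x k), `scores_wa`, `biplot` (p x k),
#'   `r2`, `adj_r2`, `prop_var`, `predictors`, `conditioned`.
#' @export
rda <- function(Y, X, Z = NULL, scale_loci = FALSE) {
  Y <- as.matrix(Y); X <- as.matrix(X)
  n <- nrow(Y); m <- ncol(Y); p <- ncol(X)
  q <- if (is.null(Z)) 0 else ncol(Z)
  if (nrow(X) != n || (q > 0 && nrow(Z) != n))
    stop("Y, X and Z must have matching rows")
  if (n <= p + q) stop("need n > p + q samples")
  pred_names <- colnames(X) %||% paste0("X", seq_len(p))

  Yc <- scale(Y, scale = scale_loci)
  Yc[is.nan(Yc)] <- 0   # constant response columns carry no variance
  Xs <- scale(X)
  if (any(is.nan(Xs)))
    stop("constant predictor column(s): ",
         paste(pred_names[apply(X, 2, stats::sd) == 0], collapse = ", "))
  absorbed <- character()
  if (!is.null(Z)) {
    Yc <- residualize(Yc, Z)
    Xs <- residualize(Xs, Z)
    # predictors lying in the span of the conditioning variables carry no
    # usable variance; they are conditioned out, not collinear with each other
    resid_ss <- colSums(Xs^2) / (n - 1)
    absorbed <- pred_names[resid_ss < 1e-16]
    Xs <- Xs[, resid_ss >= 1e-16, drop = FALSE]
  }

  if (ncol(Xs) == 0) {
    total_var <- sum(Yc^2) / (n - 1)
    loadings <- matrix(0, m, 1, dimnames = list(colnames(Y), "RDA1"))
    return(structure(list(
      eigenvalues = 0, loadings = loadings,
      scores = matrix(0, n, 1), scores_wa = matrix(0, n, 1),
      biplot = matrix(0, p, 1, dimnames = list(pred_names, "RDA1")),
      r2 = 0, adj_r2 = 0, prop_var = 0,
      constrained_variance = 0, total_variance = total_var,
      predictors = pred_names, absorbed = absorbed,
      conditioned = colnames(Z) %||% paste0("Z", seq_len(q)), n = n),
      class = "rda_result"))
  }
  qrx <- qr(Xs)
  if (qrx$rank < ncol(Xs)) {
    drop_cols <- setdiff(seq_len(ncol(Xs)), qrx$pivot[seq_len(qrx$rank)])
    stop("rank-deficient predictors; collinear column(s): ",
         paste(setdiff(pred_names, absorbed)[drop_cols], collapse = ", "))
  }
  Yhat <- qr.fitted(qrx, Yc)

  total_var <- sum(Yc^2) / (n - 1)
  k <- min(p, n - 1, m)
  s <- svd(Yhat, nu = k, nv = k)
  eig <- (s$d^2 / (n - 1))[seq_len(k)]
  keep <- eig > max(eig[1], 0) * 1e-12
  if (!any(keep)) keep <- 1
  k <- max(which(keep))
  axes <- s$v[, seq_len(k), drop = FALSE]
  fx <- fix_signs(axes)
  axes <- fx$loadings
  scores_lc <- Yhat %*% axes
  scores_wa <- Yc %*% axes
  loadings <- axes
  rownames(loadings) <- colnames(Y)
  biplot <- suppressWarnings(stats::cor(Xs, scores_lc))
  biplot[is.na(biplot)] <- 0
  rownames(biplot) <- setdiff(pred_names, absorbed)
  colnames(loadings) <- colnames(scores_lc) <- colnames(scores_wa) <-
    colnames(biplot) <- paste0("RDA", seq_len(k))
  constrained_var <- sum(s$d^2) / (n - 1)
  r2 <- if (total_var > 0) constrained_var / total_var else 0
  structure(list(
    eigenvalues = eig[seq_len(k)],
    loadings = loadings, scores = scores_lc, scores_wa = scores_wa,
    biplot = biplot,
    r2 = r2,
    adj_r2 = 1 - (1 - r2) * (n - 1) / (n - p - 1),
    prop_var = eig[seq_len(k)] / total_var,
    constrained_variance = constrained_var, total_variance = total_var,
    predictors = setdiff(pred_names, absorbed), absorbed = absorbed,
    conditioned = if (is.null(Z)) character()
                  else colnames(Z) %||% paste0("Z", seq_len(q)),
    n = n),
    class = "rda_result")
}

#' @export
print.rda_result <- function(x, ...) {
  cat("rda_result:", length(x$eigenvalues), "constrained axes,",
      length(x$predictors), "predictors",
      if (length(x$conditioned)) paste0("(conditioned on ",
                                        length(x$conditioned), ")") else "",
      "\n")
  cat(sprintf("  R2 = %.4f (adj %.4f)\n", x$r2, x$adj_r2))
  invisible(x)
}

#' Variance partitioning over named predictor sets
#'
#' For each named set (e.g. climate, population structure, geography,
#' ecotype) reports: the set's standalone R-squared, its marginal
#' R-squared (variance explained beyond all other sets: the constrained
#' variance of the partial RDA of the set conditioned on all other sets,
#' expressed as a fraction of the total response variance), and
#' Ezekiel-adjusted versions; plus a row for the full model. With
#' mutually orthogonal (centered) sets the marginal values sum exactly to
#' the full-model R-squared; a set wholly contained in the others' span
#' has marginal R-squared 0.
#'
#' @param Y response matrix (n x m).
#' @param sets named list of predictor tables (n x p_i each).
#' @return data frame, one row per set plus `"full"`.
#' @export
partial_rda_variance <- function(Y, sets) {
  stopifnot(is.list(sets), length(names(sets)) == length(sets))
  n <- nrow(Y)
  # rank-tolerant projection fit: duplicated or collinear sets are legal
  # here (the projection is onto the span, via a pivoted QR)
  fit_frac <- function(X, Z = NULL) {
    Yc <- residualize(scale(Y, scale = FALSE), Z)
    Xsc <- scale(X)
    Xsc[is.nan(Xsc)] <- 0
    Xs <- residualize(Xsc, Z)
    Xs <- Xs[, colSums(Xs^2) > 1e-12, drop = FALSE]
    total <- sum(Yc^2)
    if (ncol(Xs) == 0 || total == 0)
      return(c(constrained = 0, total = total))
    Yhat <- qr.fitted(qr(Xs), Yc)
    c(constrained = sum(Yhat^2), total = total)
  }
  Y <- as.matrix(Y)
  total_ss <- sum(scale(Y, scale = FALSE)^2)
  full_fit <- fit_frac(do.call(cbind, sets))
  full <- c(r2 = unname(full_fit["constrained"] / total_ss),
            p = ncol(do.call(cbind, sets)))
  rows <- lapply(names(sets), function(nm) {
    X_s <- do.call(cbind, sets[nm])
    alone <- c(r2 = unname(fit_frac(X_s)["constrained"] / total_ss),
               p = ncol(X_s))
    others <- setdiff(names(sets), nm)
    if (length(others)) {
      Z_o <- do.call(cbind, sets[others])
      reduced_r2 <- unname(fit_frac(Z_o)["constrained"] / total_ss)
      marginal <- unname(fit_frac(X_s, Z = Z_o)["constrained"] / total_ss)
    } else {
      reduced_r2 <- 0
      marginal <- alone["r2"]
    }
    data.frame(set = nm,
               r2_alone = unname(alone["r2"]),
               adj_r2_alone = ezekiel(alone["r2"], n, alone["p"]),
               r2_marginal = unname(marginal),
               adj_r2_marginal = ezekiel(full["r2"], n, full["p"]) -
                 if (length(others))
                   ezekiel(reduced_r2, n, full["p"] - alone["p"]) else 0,
               p = unname(alone["p"]))
  })
  out <- do.call(rbind, rows)
  out <- rbind(out, data.frame(set = "full",
                               r2_alone = unname(full["r2"]),
                               adj_r2_alone = ezekiel(full["r2"], n, full["p"]),
                               r2_marginal = unname(full["r2"]),
                               adj_r2_marginal = ezekiel(full["r2"], n, full["p"]),
                               p = unname(full["p"])))
  rownames(out) <- NULL
  out
}

ezekiel <- function(r2, n, p) unname(1 - (1 - r2) * (n - 1) / (n - p - 1))
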
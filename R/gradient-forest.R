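## From-scratch gradient forest: per-locus random-forest regressions of
## allele frequencies on environmental predictors, with every split's
## (value, impurity decrease) recorded so cumulative-importance turnover
## functions can be assembled along each predictor's gradient.
##
## Trees are classic CART regression trees: variance-reduction split
## criterion, bootstrap resampling of sites, a random predictor subset of
## size mtry at each node, minimum child size min_node. Site counts in
## this setting are tiny (tens of populations), so a carefully vectorized
## pure-R implementation is fast enough for hundreds of trees per locus.

## best variance-reducing split of y on numeric x; children >= min_node.
## Returns c(value, decrease) or NULL.
best_split_1d <- function(x, y, min_node) {
  n <- length(y)
  ord <- order(x)
  xs <- x[ord]; ys <- y[ord]
  cs <- cumsum(ys)
  S <- cs[n]
  i <- seq_len(n - 1)
  # candidate boundaries: between distinct adjacent x values, children >= min_node
  ok <- (xs[i] < xs[i + 1]) & (i >= min_node) & ((n - i) >= min_node)
  if (!any(ok)) return(NULL)
  i <- i[ok]
  # decrease in SSE = between-group sum of squares gain
  dec <- cs[i]^2 / i + (S - cs[i])^2 / (n - i) - S^2 / n
  j <- which.max(dec)
  c(value = unname((xs[i[j]] + xs[i[j] + 1]) / 2),
    decrease = unname(dec[j]))
}

## grow one regression tree; returns list(nodes, splits)
## nodes: matrix with columns var, value, left, right, pred (NA var = leaf)
fit_regression_tree <- function(X, y, mtry, min_node = 2) {
  p <- ncol(X)
  nodes <- list()
  splits_var <- integer(); splits_val <- numeric(); splits_dec <- numeric()
  grow <- function(idx) {
    node_id <- length(nodes) + 1L
    nodes[[node_id]] <<- list(var = NA_integer_, value = NA_real_,
                              left = NA_integer_, right = NA_integer_,
                              pred = mean(y[idx]))
    n <- length(idx)
    if (n < 2 * min_node || stats::var(y[idx]) == 0) return(node_id)
    vars <- if (mtry >= p) seq_len(p) else sample.int(p, mtry)
    best <- NULL; best_var <- NA_integer_
    for (v in vars) {
      cand <- best_split_1d(X[idx, v], y[idx], min_node)
      if (!is.null(cand) && (is.null(best) || cand["decrease"] > best["decrease"])) {
        best <- cand; best_var <- v
      }
    }
    if (is.null(best) || best["decrease"] <= 0) return(node_id)
    splits_var[length(splits_var) + 1L] <<- best_var
    splits_val[length(splits_val) + 1L] <<- best["value"]
    splits_dec[length(splits_dec) + 1L] <<- best["decrease"]
    go_left <- X[idx, best_var] <= best["value"]
    left_id <- grow(idx[go_left])
    right_id <- grow(idx[!go_left])
    nodes[[node_id]]$var <<- best_var
    nodes[[node_id]]$value <<- unname(best["value"])
    nodes[[node_id]]$left <<- left_id
    nodes[[node_id]]$right <<- right_id
    node_id
  }
  grow(seq_along(y))
  list(nodes = nodes,
       splits = data.frame(var = splits_var, value = splits_val,
                           decrease = splits_dec))
}

predict_tree <- function(tree, X) {
  vapply(seq_len(nrow(X)), function(i) {
    node <- tree$nodes[[1]]
    while (!is.na(node$var)) {
      node <- if (X[i, node$var] <= node$value)
        tree$nodes[[node$left]] else tree$nodes[[node$right]]
    }
    node$pred
  }, numeric(1))
}

## random forest for one locus; returns list(r2, splits)
fit_locus_forest <- function(X, y, n_trees, mtry, min_node, bootstrap) {
  n <- length(y)
  oob_sum <- numeric(n); oob_n <- integer(n)
  all_splits <- vector("list", n_trees)
  for (t in seq_len(n_trees)) {
    idx <- if (bootstrap) sample.int(n, n, replace = TRUE) else seq_len(n)
    tree <- fit_regression_tree(X[idx, , drop = FALSE], y[idx], mtry, min_node)
    all_splits[[t]] <- tree$splits
    if (bootstrap) {
      oob <- setdiff(seq_len(n), unique(idx))
      if (length(oob)) {
        oob_sum[oob] <- oob_sum[oob] + predict_tree(tree, X[oob, , drop = FALSE])
        oob_n[oob] <- oob_n[oob] + 1L
      }
    }
  }
  if (bootstrap) {
    seen <- oob_n > 0
    if (!any(seen)) return(list(r2 = -Inf, splits = NULL))
    pred <- oob_sum[seen] / oob_n[seen]
    sst <- sum((y[seen] - mean(y))^2)
    r2 <- if (sst > 0) 1 - sum((y[seen] - pred)^2) / sst else -Inf
  } else {
    # no resampling: in-sample fit (diagnostic / trace mode)
    pred <- predict_tree(fit_regression_tree(X, y, mtry, min_node), X)
    sst <- sum((y - mean(y))^2)
    r2 <- if (sst > 0) 1 - sum((y - pred)^2) / sst else -Inf
  }
  list(r2 = r2, splits = do.call(rbind, all_splits))
}

env_values <- function(env) if (inherits(env, "env_table")) env$values else as.matrix(env)

#' Fit a gradient-forest turnover model
#'
#' For each locus (response column, typically a population allele
#' frequency), fits a random forest of regression trees on the
#' environmental predictors and scores it by out-of-bag R2. Loci with
#' R2 <= 0 are discarded. Each split on predictor `p` contributes a mass
#' at its split value: the locus's impurity decreases are rescaled to sum
#' to its R2, then averaged over retained loci, so each predictor's
#' cumulative mass at +Inf equals its R2-weighted importance.
#'
#' @param freqs sites x loci response matrix, or a `freq_matrix` from
#'   [allele_frequencies()]. Missing cells are dropped per locus.
#' @param env sites x predictors [env_table()] or matrix, on the raw
#'   scale (tree splits are order-based, so standardization is
#'   unnecessary and split values stay in interpretable units).
#' @param n_trees trees per locus (default 500).
#' @param corr_threshold squared-correlation threshold used only to group
#'   correlated predictors in the reported importance table.
#' @param mtry predictors tried per split; default `max(1, floor(p/3))`.
#' @param min_node minimum child size per split (default 2).
#' @param bootstrap resample sites with replacement per tree (default
#'   TRUE; FALSE fits each tree on all sites, with in-sample R2, for
#'   hand-traceable diagnostics).
#' @param seed integer seed; fits are deterministic given the seed.
#' @return object of class `turnover_model`: per-predictor sorted split
#'   masses (`splits`), `importance` (R2-weighted), `locus_r2`,
#'   `retained` locus ids, `predictor_groups` (by `corr_threshold`),
#'   `n_trees`, `seed`, `response_level`.
#' @export
fit_gradient_forest <- function(freqs, env, n_trees = 500,
                                corr_threshold = 0.5, mtry = NULL,
                                min_node = 2, bootstrap = TRUE, seed = 1) {
  Y <- if (inherits(freqs, "freq_matrix")) freqs$freq else as.matrix(freqs)
  X <- env_values(env)
  if (nrow(Y) != nrow(X)) stop("freqs and env must share sites")
  if (nrow(X) < 5) stop("need at least 5 sites")
  if (anyNA(X)) stop("env predictors must be complete")
  p <- ncol(X)
  predictors <- colnames(X) %||% paste0("V", seq_len(p))
  colnames(X) <- predictors
  if (is.null(mtry)) mtry <- max(1, floor(p / 3))
  loci <- colnames(Y) %||% paste0("L", seq_len(ncol(Y)))
  set.seed(seed)
  locus_r2 <- stats::setNames(numeric(ncol(Y)), loci)
  locus_splits <- vector("list", ncol(Y))
  for (l in seq_len(ncol(Y))) {
    ok <- !is.na(Y[, l])
    if (sum(ok) < 5) { locus_r2[l] <- -Inf; next }
    fit <- fit_locus_forest(X[ok, , drop = FALSE], Y[ok, l],
                            n_trees, mtry, min_node, bootstrap)
    locus_r2[l] <- fit$r2
    locus_splits[[l]] <- fit$splits
  }
  retained <- which(locus_r2 > 0)
  if (!length(retained))
    stop("no signal: every locus has out-of-bag R2 <= 0 (max R2 = ",
         signif(max(locus_r2), 3), " over ", ncol(Y), " loci)")
  # per-locus normalization: masses sum to the locus R2; then average
  masses <- lapply(retained, function(l) {
    s <- locus_splits[[l]]
    s$mass <- s$decrease / sum(s$decrease) * locus_r2[l] / length(retained)
    s
  })
  all_masses <- do.call(rbind, masses)
  splits <- lapply(seq_len(p), function(v) {
    s <- all_masses[all_masses$var == v, c("value", "mass"), drop = FALSE]
    s <- stats::aggregate(mass ~ value, data = s, FUN = sum)
    s[order(s$value), , drop = FALSE]
  })
  names(splits) <- predictors
  importance <- vapply(splits, function(s) sum(s$mass), numeric(1))
  # group predictors whose squared correlation exceeds corr_threshold
  r2 <- suppressWarnings(stats::cor(X))^2
  grp <- seq_len(p)
  for (i in seq_len(p)) for (j in seq_len(p)) {
    if (j > i && !is.na(r2[i, j]) && r2[i, j] > corr_threshold)
      grp[grp == grp[j]] <- grp[i]
  }
  structure(list(
    predictors = predictors, splits = splits, importance = importance,
    locus_r2 = locus_r2[retained], retained = loci[retained],
    predictor_groups = stats::setNames(match(grp, unique(grp)), predictors),
    env_range = apply(X, 2, range),
    n_trees = n_trees, mtry = mtry, seed = seed,
    response_level = if (inherits(freqs, "freq_matrix"))
      "population_freq" else "matrix"),
    class = "turnover_model")
}

#' @export
print.turnover_model <- function(x, ...) {
  cat("turnover_model:", length(x$retained), "retained loci,",
      x$n_trees, "trees/locus\n")
  imp <- sort(x$importance, decreasing = TRUE)
  cat("  importance:",
      paste(sprintf("%s=%.4g", names(imp)[seq_len(min(5, length(imp)))],
                    imp[seq_len(min(5, length(imp)))]), collapse = ", "),
      "\n")
  invisible(x)
}

#' Turnover function: cumulative genetic importance along a predictor
#'
#' `F_p(v)` sums the importance masses of all splits on predictor `p`
#' with split value `<= v`: a non-decreasing right-continuous step
#' function rising from 0 to the predictor's R2-weighted importance. It
#' transforms an environmental value into "genetic importance" units.
#'
#' @param model a [fit_gradient_forest()] model.
#' @param predictor predictor name.
#' @param value numeric vector of environmental values.
#' @return numeric vector of cumulative importance.
#' @export
turnover <- function(model, predictor, value) {
  if (!predictor %in% model$predictors)
    stop("unknown predictor: ", predictor)
  s <- model$splits[[predictor]]
  if (!nrow(s)) return(rep(0, length(value)))
  cum <- cumsum(s$mass)
  idx <- findInterval(value, s$value)
  ifelse(idx == 0, 0, cum[pmax(idx, 1)])
}

#' Genomic offset between current and future climate
#'
#' Euclidean distance, in turnover-transformed (genetic-importance)
#' space, between a site's current and future climate:
#' `sqrt(sum_p (F_p(future) - F_p(current))^2)`. Zero when the future
#' equals the present; with a single predictor it reduces to the absolute
#' change in that predictor's cumulative importance.
#'
#' @param model a [fit_gradient_forest()] model.
#' @param env_current,env_future [env_table()]s (or matrices) on the raw
#'   predictor scale, sharing site ids/rows.
#' @param predictors predictors to include (default: bio5 if fitted,
#'   otherwise all fitted predictors).
#' @return data frame (`site`, `offset`), class `offset_map`.
#' @export
genomic_offset <- function(model, env_current, env_future,
                           predictors = NULL) {
  if (is.null(predictors))
    predictors <- if ("bio5" %in% model$predictors) "bio5" else model$predictors
  missing_p <- setdiff(predictors, model$predictors)
  if (length(missing_p))
    stop("model was not fitted with predictor(s): ",
         paste(missing_p, collapse = ", "))
  cur <- env_values(env_current); fut <- env_values(env_future)
  for (tab in list(cur, fut)) {
    if (!all(predictors %in% colnames(tab)))
      stop("environment layer lacks predictor(s): ",
           paste(setdiff(predictors, colnames(tab)), collapse = ", "))
  }
  ids <- rownames(cur) %||% as.character(seq_len(nrow(cur)))
  if (!identical(nrow(cur), nrow(fut)))
    stop("current and future layers must share sites")
  if (!is.null(rownames(fut)) && !identical(rownames(cur), rownames(fut)))
    fut <- fut[match(rownames(cur), rownames(fut)), , drop = FALSE]
  d2 <- 0
  for (pr in predictors) {
    dF <- turnover(model, pr, fut[, pr]) - turnover(model, pr, cur[, pr])
    d2 <- d2 + dF^2
  }
  out <- data.frame(site = ids, offset = sqrt(d2))
  class(out) <- c("offset_map", "data.frame")
  out
}

#' Genomic offset recomputed per ecotype group
#'
#' In locations where two reproductive ecotypes co-occur, allele
#' frequencies at the candidate loci are recalculated for each
#' population x ecotype group separately, the gradient forest is refit on
#' the group-level frequencies, and offsets are reported per group, so
#' that the climate vulnerability of co-occurring ecotypes can be
#' compared.
#'
#' @param gm a [genotype_matrix()] with ecotype labels.
#' @param outlier_ids candidate locus ids to use as responses.
#' @param env_current,env_future [env_table()]s whose rows are the
#'   ecotype groups (ids `"<population>.<ecotype>"`) or the populations
#'   (values are then reused for each ecotype of the population).
#' @param ... further arguments to [fit_gradient_forest()].
#' @return data frame (`site`, `offset`, `population`, `ecotype`).
#' @export
ecotype_offsets <- function(gm, outlier_ids, env_current, env_future, ...) {
  idx <- match(outlier_ids, gm$loci$id)
  if (anyNA(idx)) stop("outlier loci missing from genotype matrix")
  gm_sub <- subset_gm(gm, loc_keep = seq_len(ncol(gm$dosage)) %in% idx)
  eco <- ifelse(is.na(gm_sub$individuals$ecotype) |
                  gm_sub$individuals$ecotype == "none",
                "all", gm_sub$individuals$ecotype)
  grp <- paste(gm_sub$individuals$population, eco, sep = ".")
  names(grp) <- gm_sub$individuals$id
  freqs <- allele_frequencies(gm_sub, grouping = grp)
  expand_env <- function(env) {
    vals <- env_values(env)
    if (all(freqs$groups %in% rownames(vals))) {
      vals[freqs$groups, , drop = FALSE]
    } else {
      pops <- sub("\\.[^.]+$", "", freqs$groups)
      if (!all(pops %in% rownames(vals)))
        stop("environment rows match neither groups nor populations")
      out <- vals[pops, , drop = FALSE]
      rownames(out) <- freqs$groups
      out
    }
  }
  cur <- expand_env(env_current); fut <- expand_env(env_future)
  model <- fit_gradient_forest(freqs$freq, cur, ...)
  off <- genomic_offset(model, cur, fut)
  off$population <- sub("\\.[^.]+$", "", off$site)
  off$ecotype <- sub("^.*\\.", "", off$site)
  off
}
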
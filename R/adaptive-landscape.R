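#' Adaptively enriched RDA on candidate loci
#'
#' Re-runs the constrained ordination using only candidate loci as
#' responses and the climate variables retained for projection (by
#' default the two temperature and two precipitation variables, after
#' excluding idiosyncratic lake variables such as surface area and pH and
#' the loci most strongly associated with them), conditioned on
#' population structure.
#'
#' @param gm_imputed imputed [genotype_matrix()].
#' @param outliers an [assign_env()]-annotated outlier table.
#' @param env an [env_table()] restricted to the projection variables
#'   (rows = populations or individuals), standardized.
#' @param structure_pcs matrix of population-structure covariates
#'   (e.g. first three genotype PCs), rows matching individuals.
#' @param exclude_variables loci whose `best_variable` is one of these are
#'   dropped before the fit (default `c("surface_area", "pH")`).
#' @return an [rda()] result restricted to the enriched locus set; the
#'   locus ids used are in `attr(, "loci")`.
#' @export
adaptive_enriched_rda <- function(gm_imputed, outliers, env, structure_pcs,
                                  exclude_variables = c("surface_area", "pH")) {
  if (!"best_variable" %in% names(outliers))
    stop("outliers must carry best_variable; run assign_env() first")
  keep <- !(outliers$best_variable %in% exclude_variables)
  loci_keep <- outliers$locus_id[keep]
  if (!length(loci_keep))
    stop("no adaptive loci remain after excluding variables: ",
         paste(exclude_variables, collapse = ", "))
  idx <- match(loci_keep, gm_imputed$loci$id)
  Y <- gm_imputed$dosage[, idx, drop = FALSE]
  E <- if (all(gm_imputed$individuals$population %in% env$ids)) {
    broadcast_env(env, gm_imputed$individuals$population)
  } else {
    env$values[match(gm_imputed$individuals$id, env$ids), , drop = FALSE]
  }
  fit <- rda(Y, E, Z = structure_pcs)
  attr(fit, "loci") <- loci_keep
  fit
}

#' Project the adaptive index across an environmental grid
#'
#' The adaptive index of a cell on a given RDA axis is the dot product of
#' the axis's variable (biplot) scores with the cell's standardized
#' climate: a linear map from climate space to the adaptively enriched
#' genetic space. The grid must be standardized with the recent
#' sampling-site reference so map values are comparable with sample
#' scores; a cell sitting at the mean climate scores exactly 0.
#'
#' @param rda_fit an [adaptive_enriched_rda()] (or any [rda()]) result.
#' @param axis axis number (1-based).
#' @param grid_env an [env_table()] over grid cells, standardized with
#'   the recent reference, containing every predictor of the fit.
#' @return data frame (`cell_id`, `x`, `y` when coordinates are attached,
#'   `axis`, `index`).
#' @export
adaptive_index <- function(rda_fit, axis = 1, grid_env) {
  if (axis > ncol(rda_fit$biplot))
    stop("axis ", axis, " exceeds fitted axes (", ncol(rda_fit$biplot), ")")
  vars <- rda_fit$predictors
  missing_vars <- setdiff(vars, colnames(grid_env$values))
  if (length(missing_vars))
    stop("grid lacks predictor(s): ", paste(missing_vars, collapse = ", "))
  if (is.null(grid_env$standardization))
    warning("grid environment is not standardized; index values will not ",
            "be comparable with sample scores")
  Z <- grid_env$values[, vars, drop = FALSE]
  idx <- as.numeric(Z %*% rda_fit$biplot[vars, axis])
  coords <- attr(grid_env, "coords")
  out <- data.frame(cell_id = grid_env$ids, axis = axis, index = idx)
  if (!is.null(coords)) {
    m <- match(out$cell_id, coords$cell)
    out$x <- coords$x[m]; out$y <- coords$y[m]
    out <- out[, c("cell_id", "x", "y", "axis", "index")]
  }
  out
}
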
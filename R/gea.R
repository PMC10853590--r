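#' Detect candidate loci from RDA loadings
#'
#' On each of the first `n_axes` constrained axes, locus loadings are
#' converted to z-scores (per axis); loci with `|z| > sd_cutoff` on any
#' axis form the candidate set (a 3 SD cutoff corresponds to a two-tailed
#' standard-normal tail probability of about 0.0027). A locus exceeding
#' the cutoff on several axes is reported once, attributed to its
#' max-|z| axis.
#'
#' @param rda_fit an [rda()] result.
#' @param n_axes number of leading axes scanned (default 3).
#' @param sd_cutoff z-score cutoff (default 3, strict `>`).
#' @return data frame of class `outlier_set` (`locus_id`, `axis`,
#'   `loading`, `z`), one row per detected locus.
#' @export
detect_outliers <- function(rda_fit, n_axes = 3, sd_cutoff = 3) {
  L <- rda_fit$loadings
  if (ncol(L) < n_axes)
    stop("RDA has ", ncol(L), " axes; n_axes = ", n_axes, " requested")
  L <- L[, seq_len(n_axes), drop = FALSE]
  sds <- apply(L, 2, stats::sd)
  if (any(sds == 0))
    stop("degenerate axis with zero loading SD: axis ",
         paste(which(sds == 0), collapse = ", "))
  z <- scale(L)
  hit <- abs(z) > sd_cutoff
  detected <- which(rowSums(hit) > 0)
  if (!length(detected)) {
    out <- data.frame(locus_id = character(), axis = integer(),
                      loading = numeric(), z = numeric())
    class(out) <- c("outlier_set", "data.frame")
    return(out)
  }
  best_axis <- apply(abs(z[detected, , drop = FALSE]), 1, which.max)
  ids <- rownames(L) %||% as.character(seq_len(nrow(L)))
  out <- data.frame(
    locus_id = ids[detected],
    axis = as.integer(best_axis),
    loading = L[cbind(detected, best_axis)],
    z = z[cbind(detected, best_axis)])
  class(out) <- c("outlier_set", "data.frame")
  out
}

#' Assign each candidate locus to its best environmental variable
#'
#' Pearson correlation of individual dosages with each environmental
#' variable (site-level values broadcast to individuals through their
#' population); the variable with the largest |r| wins, ties broken by
#' variable order. Constant loci (correlation undefined) are flagged and
#' excluded.
#'
#' @param outliers a [detect_outliers()] table.
#' @param gm_imputed imputed [genotype_matrix()] (no missing entries).
#' @param env an [env_table()] (rows = populations or individuals).
#' @param variables variables to score (default: all in `env`).
#' @return the outlier table with `best_variable`, `best_r`, `best_r2`
#'   columns; excluded constant loci recorded in
#'   `attr(, "excluded_constant")`.
#' @export
assign_env <- function(outliers, gm_imputed, env,
                       variables = colnames(env$values)) {
  if (!nrow(outliers)) {
    outliers$best_variable <- character()
    outliers$best_r <- outliers$best_r2 <- numeric()
    return(outliers)
  }
  idx <- match(outliers$locus_id, gm_imputed$loci$id)
  if (anyNA(idx)) stop("outlier loci missing from genotype matrix")
  E <- if (all(gm_imputed$individuals$population %in% env$ids)) {
    broadcast_env(env, gm_imputed$individuals$population)
  } else {
    env$values[match(gm_imputed$individuals$id, env$ids), , drop = FALSE]
  }
  E <- E[, variables, drop = FALSE]
  D <- gm_imputed$dosage[, idx, drop = FALSE]
  constant <- apply(D, 2, stats::sd) == 0
  r <- suppressWarnings(stats::cor(D, E))   # loci x variables
  # first max = tie-break by variable order; constant loci (all-NA row)
  # get a placeholder and are dropped below
  best_j <- apply(abs(r), 1, function(v)
    if (all(is.na(v))) 1L else which.max(v))
  outliers$best_variable <- variables[best_j]
  outliers$best_r <- r[cbind(seq_len(nrow(r)), best_j)]
  outliers$best_r2 <- outliers$best_r^2
  excluded <- outliers$locus_id[constant]
  out <- outliers[!constant, , drop = FALSE]
  attr(out, "excluded_constant") <- excluded
  out
}

#' Strong candidate loci
#'
#' Subsets candidates whose squared correlation with their best
#' environmental variable exceeds `r2_min` (strict inequality: exactly
#' 0.5 is not strong).
#'
#' @param outliers an [assign_env()]-annotated outlier table.
#' @param r2_min threshold on `best_r2` (default 0.5).
#' @return the strong subset with a `strong` flag column set to `TRUE`.
#' @export
strong_candidates <- function(outliers, r2_min = 0.5) {
  if (!"best_r2" %in% names(outliers))
    stop("run assign_env() before strong_candidates()")
  out <- outliers[!is.na(outliers$best_r2) & outliers$best_r2 > r2_min, ,
                  drop = FALSE]
  out$strong <- rep(TRUE, nrow(out))
  out
}

#' Nearest-gene annotation of candidate loci
#'
#' Loci inside a gene interval get that gene at distance 0 (`inside`);
#' intergenic loci get the nearest gene on the same chromosome by edge
#' distance, labelled `upstream` (gene before the locus) or `downstream`
#' (gene after). Equidistant ties go to the lower-coordinate gene. Only
#' GFF3 features of type `gene` are indexed; loci on chromosomes without
#' genes yield a `no_gene` row.
#'
#' @param outliers an outlier table with `locus_id`.
#' @param gff_path GFF3 file.
#' @param loci locus coordinate table (e.g. `gm$loci`) mapping locus ids
#'   to `chrom`/`pos`.
#' @return data frame (`locus_id`, `gene_id`, `distance`, `relation`).
#' @export
annotate_nearest_gene <- function(outliers, gff_path, loci) {
  gff <- rtracklayer::import(gff_path)
  genes <- gff[gff$type == "gene"]
  gene_id <- genes$ID %||% genes$Name %||% as.character(seq_along(genes))
  gene_df <- data.frame(
    id = gene_id,
    chrom = as.character(GenomicRanges::seqnames(genes)),
    start = GenomicRanges::start(genes),
    end = GenomicRanges::end(genes))
  idx <- match(outliers$locus_id, loci$id)
  if (anyNA(idx)) stop("outlier loci missing from locus table")
  rows <- lapply(seq_along(idx), function(i) {
    chrom <- loci$chrom[idx[i]]; pos <- loci$pos[idx[i]]
    g <- gene_df[gene_df$chrom == chrom, , drop = FALSE]
    if (!nrow(g))
      return(data.frame(locus_id = outliers$locus_id[i],
                        gene_id = "no_gene", distance = NA_real_,
                        relation = "no_gene"))
    inside <- pos >= g$start & pos <= g$end
    if (any(inside)) {
      j <- which(inside)[order(g$start[inside])][1]
      return(data.frame(locus_id = outliers$locus_id[i], gene_id = g$id[j],
                        distance = 0, relation = "inside"))
    }
    dist <- pmin(abs(pos - g$start), abs(pos - g$end))
    best <- which(dist == min(dist))
    j <- best[order(g$start[best])][1]   # equidistant -> lower coordinate
    data.frame(locus_id = outliers$locus_id[i], gene_id = g$id[j],
               distance = dist[j],
               relation = if (g$end[j] < pos) "upstream" else "downstream")
  })
  do.call(rbind, rows)
}
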
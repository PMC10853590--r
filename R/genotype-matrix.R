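#' Construct a genotype matrix
#'
#' The central container of the package: an individuals x loci matrix of
#' alternate-allele dosages (0, 1, 2 or `NA` for missing), together with
#' individual metadata (population and optional ecotype labels), locus
#' metadata (coordinates, alleles, variant class) and a provenance log of
#' every filter applied.
#'
#' @param dosage numeric matrix, individuals in rows, loci in columns;
#'   entries in `{0, 1, 2, NA}`.
#' @param individuals data frame with at least column `id`; optional
#'   `population` and `ecotype` columns.
#' @param loci data frame with columns `id`, `chrom`, `pos` (1-based),
#'   `ref`, `alt`, `class` (one of `"SNP"`, `"DEL"`, `"DUP"`, `"INS"`,
#'   `"INV"`, `"BND"`) and optional `biallelic` / `is_indel` flags.
#' @param support optional integer matrix (same shape as `dosage`) of
#'   per-genotype read-support counts (e.g. paired-end reads backing an
#'   SV genotype).
#' @param log list of filter records; normally left empty at construction.
#'
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage, individuals, loci, support = NULL,
                            log = list()) {
  dosage <- as.matrix(dosage)
  stopifnot(is.data.frame(individuals), is.data.frame(loci))
  if (nrow(dosage) != nrow(individuals))
    stop("dosage rows (", nrow(dosage), ") != individuals (",
         nrow(individuals), ")")
  if (ncol(dosage) != nrow(loci))
    stop("dosage columns (", ncol(dosage), ") != loci (", nrow(loci), ")")
  bad <- dosage[!is.na(dosage)]
  if (length(bad) && !all(bad %in% c(0, 1, 2)))
    stop("dosage entries must be 0, 1, 2 or NA")
  if (!"id" %in% names(individuals)) stop("individuals needs an 'id' column")
  for (col in c("id", "chrom", "pos")) {
    if (!col %in% names(loci)) stop("loci needs a '", col, "' column")
  }
  if (any(loci$pos < 1)) stop("locus positions are 1-based and must be >= 1")
  key <- paste(loci$chrom, loci$pos, loci$alt %||% "", sep = ":")
  if (anyDuplicated(key)) stop("duplicate (chrom, pos, alt) locus keys")
  if (!"population" %in% names(individuals)) individuals$population <- NA_character_
  if (!"ecotype" %in% names(individuals)) individuals$ecotype <- NA_character_
  if (!"class" %in% names(loci)) loci$class <- "SNP"
  rownames(dosage) <- individuals$id
  colnames(dosage) <- loci$id
  if (!is.null(support)) {
    support <- as.matrix(support)
    stopifnot(all(dim(support) == dim(dosage)))
    rownames(support) <- individuals$id
    colnames(support) <- loci$id
  }
  structure(
    list(dosage = dosage, individuals = individuals, loci = loci,
         support = support, log = log),
    class = "genotype_matrix"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$dosage), "individuals x",
      ncol(x$dosage), "loci\n")
  cls <- table(x$loci$class)
  cat("  classes:", paste(names(cls), cls, sep = "=", collapse = ", "), "\n")
  cat(sprintf("  missing: %.2f%%\n", 100 * mean(is.na(x$dosage))))
  if (length(x$log)) {
    cat("  filter log:\n")
    for (rec in x$log)
      cat(sprintf("    %-22s removed %d, kept %d\n",
                  rec$op, rec$removed, rec$retained))
  }
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Number of individuals / loci
#' @param gm a [genotype_matrix()]
#' @return integer count.
#' @export
n_individuals <- function(gm) nrow(gm$dosage)

#' @rdname n_individuals
#' @export
n_loci <- function(gm) ncol(gm$dosage)

## internal: subset keeping metadata and support in sync, appending a log
## record with the removed/retained counts for the provenance invariant
subset_gm <- function(gm, ind_keep = NULL, loc_keep = NULL, op = NULL) {
  if (is.null(ind_keep)) ind_keep <- rep(TRUE, nrow(gm$dosage))
  if (is.null(loc_keep)) loc_keep <- rep(TRUE, ncol(gm$dosage))
  log <- gm$log
  if (!is.null(op)) {
    removed <- if (all(ind_keep)) sum(!loc_keep) else sum(!ind_keep)
    retained <- if (all(ind_keep)) sum(loc_keep) else sum(ind_keep)
    log <- c(log, list(list(op = op, removed = removed, retained = retained)))
  }
  genotype_matrix(
    gm$dosage[ind_keep, loc_keep, drop = FALSE],
    gm$individuals[ind_keep, , drop = FALSE],
    gm$loci[loc_keep, , drop = FALSE],
    support = if (!is.null(gm$support))
      gm$support[ind_keep, loc_keep, drop = FALSE],
    log = log
  )
}

#' Attach population / ecotype labels to a genotype matrix
#'
#' @param gm a [genotype_matrix()].
#' @param populations data frame with columns `id`, `population` and
#'   optionally `ecotype`, one row per individual.
#' @return the genotype matrix with labels filled in.
#' @export
set_populations <- function(gm, populations) {
  stopifnot(all(c("id", "population") %in% names(populations)))
  idx <- match(gm$individuals$id, populations$id)
  if (anyNA(idx))
    stop("individuals missing from population table: ",
         paste(gm$individuals$id[is.na(idx)][1:5], collapse = ", "))
  gm$individuals$population <- populations$population[idx]
  if ("ecotype" %in% names(populations))
    gm$individuals$ecotype <- populations$ecotype[idx]
  gm
}
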
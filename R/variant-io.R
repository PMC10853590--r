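#' Read a VCF into a genotype matrix
#'
#' Diploid `GT` calls are mapped to alternate-allele dosages
#' (`0/0 -> 0`, `0/1` or `1/0 -> 1`, `1/1 -> 2`, `./. -> NA`). Phased
#' separators (`|`) are accepted. The variant class is taken from
#' `INFO/SVTYPE` when present, otherwise `SNP`. Multi-allelic records and
#' indels are kept but flagged so [filter_sites()] can drop them.
#'
#' @param path VCF 4.x file (uncompressed or gzipped).
#' @param support_field optional FORMAT field (e.g. `"SR"`) holding
#'   per-genotype read-support counts; stored in `$support`.
#' @return a [genotype_matrix()].
#' @export
read_vcf <- function(path, support_field = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  fmt_keys <- unique(unlist(strsplit(fix$FORMAT %||% v@gt[, "FORMAT"], ":")))
  gt <- vcfR::extract.gt(v, element = "GT")
  if (all(is.na(gt))) stop("VCF has no GT field")
  gt_clean <- gsub("\\|", "/", gt)
  ploidy_bad <- !is.na(gt_clean) & !grepl("^[0-9.]+/[0-9.]+$", gt_clean)
  if (any(ploidy_bad))
    stop("non-diploid genotype encountered (e.g. '",
         gt_clean[which(ploidy_bad)[1]], "'); only diploid GT is supported")
  a1 <- sub("/.*", "", gt_clean)
  a2 <- sub(".*/", "", gt_clean)
  dos <- suppressWarnings((as.numeric(a1) > 0) + (as.numeric(a2) > 0))
  dosage <- matrix(dos, nrow = nrow(gt), dimnames = dimnames(gt))
  # loci in rows from vcfR; transpose to individuals x loci
  dosage <- t(dosage)

  svtype <- vcfR::extract.info(v, element = "SVTYPE")
  alt <- fix$ALT
  class <- ifelse(!is.na(svtype), svtype, "SNP")
  multi <- grepl(",", alt)
  symbolic <- grepl("^<", alt)
  is_indel <- !symbolic & !multi &
    (nchar(fix$REF) != 1 | nchar(alt) != 1) & is.na(svtype)
  ids <- fix$ID
  if (any(is.na(ids) | ids == "."))
    ids <- ifelse(is.na(ids) | ids == ".",
                  paste0(fix$CHROM, ":", fix$POS, "_", alt), ids)
  loci <- data.frame(id = ids, chrom = fix$CHROM, pos = as.integer(fix$POS),
                     ref = fix$REF, alt = alt, class = class,
                     biallelic = !multi, is_indel = is_indel)
  individuals <- data.frame(id = rownames(dosage))

  support <- NULL
  if (!is.null(support_field)) {
    sv_rows <- !is.na(svtype)
    if (!support_field %in% fmt_keys)
      stop("support field '", support_field, "' absent from VCF FORMAT")
    sup <- vcfR::extract.gt(v, element = support_field, as.numeric = TRUE)
    support <- t(sup)
  }
  genotype_matrix(dosage, individuals, loci, support = support)
}

#' Site-level filtering
#'
#' Drops non-biallelic records and indels (when `biallelic_only`), then
#' loci whose missing-genotype fraction is `>= max_site_missing` ("less
#' than 30% missing" retained, at the default). SV classes are never
#' treated as indels. The filter log records removed/retained counts.
#'
#' @param gm a [genotype_matrix()].
#' @param biallelic_only drop multi-allelic records and indels.
#' @param max_site_missing loci with missing fraction at or above this are
#'   removed (default 0.30).
#' @return filtered [genotype_matrix()].
#' @export
filter_sites <- function(gm, biallelic_only = TRUE, max_site_missing = 0.30) {
  stopifnot(max_site_missing >= 0, max_site_missing <= 1)
  keep <- rep(TRUE, ncol(gm$dosage))
  if (biallelic_only) {
    if ("biallelic" %in% names(gm$loci)) keep <- keep & gm$loci$biallelic
    if ("is_indel" %in% names(gm$loci))
      keep <- keep & !(gm$loci$is_indel & gm$loci$class == "SNP")
  }
  miss <- colMeans(is.na(gm$dosage))
  keep <- keep & miss < max_site_missing
  subset_gm(gm, loc_keep = keep, op = "filter_sites")
}

#' Individual-level missingness filter
#'
#' Removes individuals with a missing-genotype fraction strictly greater
#' than `max_ind_missing` across the current locus set.
#'
#' @param gm a [genotype_matrix()].
#' @param max_ind_missing removal threshold (default 0.30, strict `>`).
#' @return filtered [genotype_matrix()].
#' @export
filter_individuals <- function(gm, max_ind_missing = 0.30) {
  miss <- rowMeans(is.na(gm$dosage))
  subset_gm(gm, ind_keep = miss <= max_ind_missing,
            op = "filter_individuals")
}

#' Recode weakly supported genotypes as missing
#'
#' Genotypes backed by fewer than `min_support` supporting reads (e.g.
#' paired-end reads supporting an SV call) are set to missing. Callers
#' typically re-apply [filter_sites()] afterwards with the stricter SV
#' missingness ceiling (0.20).
#'
#' @param gm a [genotype_matrix()] with a support matrix.
#' @param min_support minimum supporting reads to keep a genotype
#'   (default 3; a count of exactly 3 is kept).
#' @param support_field name of the support field, for error messages.
#' @return the recoded [genotype_matrix()].
#' @export
recode_low_support <- function(gm, min_support = 3, support_field = "SR") {
  if (is.null(gm$support))
    stop("support field '", support_field,
         "' not present; read the VCF with support_field = \"",
         support_field, "\"")
  low <- !is.na(gm$dosage) & (is.na(gm$support) | gm$support < min_support)
  gm$dosage[low] <- NA
  gm$log <- c(gm$log, list(list(op = "recode_low_support",
                                removed = sum(low),
                                retained = sum(!is.na(gm$dosage)))))
  gm
}

## pairwise squared correlations of dosage columns, pairwise-complete
pairwise_r2 <- function(d) {
  suppressWarnings(stats::cor(d, use = "pairwise.complete.obs"))^2
}

#' LD pruning in sliding windows
#'
#' Within windows of `window_bp` (anchored at absolute coordinates and
#' sliding by half a window, so results do not depend on which loci were
#' removed earlier and the operation is idempotent), a greedy
#' left-to-right scan removes the later locus of any pair whose squared
#' Pearson dosage correlation (pairwise-complete over non-missing
#' individuals) exceeds `r2_threshold`.
#'
#' @param gm a [genotype_matrix()] with loci sorted by (chrom, pos).
#' @param r2_threshold squared-correlation threshold (default 0.5,
#'   strict `>`).
#' @param window_bp window width in base pairs (default 200 kb).
#' @return pruned [genotype_matrix()].
#' @export
ld_prune <- function(gm, r2_threshold = 0.5, window_bp = 200000) {
  ord <- order(gm$loci$chrom, gm$loci$pos)
  if (!identical(ord, seq_along(ord)))
    stop("loci must be sorted by (chrom, pos) before LD pruning")
  removed <- rep(FALSE, ncol(gm$dosage))
  half <- window_bp / 2
  for (chr in unique(gm$loci$chrom)) {
    on_chr <- which(gm$loci$chrom == chr)
    pos <- gm$loci$pos[on_chr]
    starts <- seq(floor(min(pos) / half) * half, max(pos), by = half)
    for (s in starts) {
      in_win <- on_chr[pos >= s & pos < s + window_bp]
      in_win <- in_win[!removed[in_win]]
      if (length(in_win) < 2) next
      r2 <- pairwise_r2(gm$dosage[, in_win, drop = FALSE])
      for (i in seq_along(in_win)) {
        if (removed[in_win[i]]) next
        for (j in seq_along(in_win)) {
          if (j <= i || removed[in_win[j]]) next
          if (!is.na(r2[i, j]) && r2[i, j] > r2_threshold)
            removed[in_win[j]] <- TRUE
        }
      }
    }
  }
  subset_gm(gm, loc_keep = !removed, op = "ld_prune")
}

#' Exclude loci falling in BED intervals
#'
#' BED intervals are 0-based half-open; a 1-based locus position `p` falls
#' in `(start, end]`, i.e. it is removed when `p >= start + 1` and
#' `p <= end`. Used to drop variants in repetitive regions.
#'
#' @param gm a [genotype_matrix()].
#' @param bed_path BED file (first three columns used).
#' @return filtered [genotype_matrix()].
#' @export
exclude_regions <- function(gm, bed_path) {
  bed <- utils::read.table(bed_path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)[, 1:3]
  names(bed) <- c("chrom", "start", "end")
  regions <- GenomicRanges::GRanges(
    bed$chrom, IRanges::IRanges(start = bed$start + 1, end = bed$end))
  loci <- GenomicRanges::GRanges(
    gm$loci$chrom, IRanges::IRanges(start = gm$loci$pos, width = 1))
  hit <- IRanges::overlapsAny(loci, regions)
  subset_gm(gm, loc_keep = !hit, op = "exclude_regions")
}

#' Impute missing genotypes with the locus mode
#'
#' Each missing entry is replaced by the most common dosage at that locus
#' among non-missing individuals; ties are broken toward the smallest
#' dosage so imputation is deterministic.
#'
#' @param gm a [genotype_matrix()].
#' @return a [genotype_matrix()] with no missing entries.
#' @export
impute_mode <- function(gm) {
  d <- gm$dosage
  all_missing <- colSums(!is.na(d)) == 0
  if (any(all_missing))
    stop("cannot impute loci with all genotypes missing: ",
         paste(gm$loci$id[all_missing][1:5], collapse = ", "))
  n_imputed <- 0L
  for (j in which(colSums(is.na(d)) > 0)) {
    tab <- tabulate(d[, j] + 1L, nbins = 3L)
    mode <- which.max(tab) - 1L   # which.max takes the first (smallest) tie
    miss <- is.na(d[, j])
    d[miss, j] <- mode
    n_imputed <- n_imputed + sum(miss)
  }
  gm$dosage <- d
  gm$log <- c(gm$log, list(list(op = "impute_mode", removed = 0L,
                                retained = ncol(d),
                                imputed = n_imputed)))
  gm
}

#' Group-level alternate-allele frequencies
#'
#' For each group (population, or population x ecotype) and locus,
#' frequency = alt alleles / (2 x non-missing genotypes). Groups with no
#' genotyped individual at a locus get a missing cell.
#'
#' @param gm a [genotype_matrix()].
#' @param grouping named character vector mapping individual id to group,
#'   or a column name in `gm$individuals` (default `"population"`).
#' @return object of class `freq_matrix`: list with `freq`
#'   (groups x loci), `n_alleles` (non-missing allele counts) and `groups`.
#' @export
allele_frequencies <- function(gm, grouping = "population") {
  if (is.character(grouping) && length(grouping) == 1 &&
      grouping %in% names(gm$individuals)) {
    grp <- gm$individuals[[grouping]]
  } else {
    grp <- grouping[gm$individuals$id]
    if (anyNA(grp)) stop("grouping lacks some individuals")
  }
  groups <- sort(unique(grp))
  d <- gm$dosage
  freq <- matrix(NA_real_, length(groups), ncol(d),
                 dimnames = list(groups, colnames(d)))
  n_alleles <- matrix(0L, length(groups), ncol(d),
                      dimnames = dimnames(freq))
  for (g in seq_along(groups)) {
    rows <- grp == groups[g]
    dg <- d[rows, , drop = FALSE]
    n <- colSums(!is.na(dg)) * 2L
    s <- colSums(dg, na.rm = TRUE)
    f <- ifelse(n > 0, s / n, NA_real_)
    freq[g, ] <- f
    n_alleles[g, ] <- n
  }
  structure(list(freq = freq, n_alleles = n_alleles, groups = groups),
            class = "freq_matrix")
}

#' Write the dosage matrix as CSV
#' @param gm a [genotype_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dosage_csv <- function(gm, path) {
  df <- data.frame(id = gm$individuals$id,
                   population = gm$individuals$population,
                   gm$dosage, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
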
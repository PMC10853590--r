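#' Environmental variable tables
#'
#' An `env_table` holds sites (or individuals) x environmental variables,
#' a layer label (`"recent"` or `"future:<scenario>"`) and, once
#' standardized, the per-variable means and standard deviations used.
#' Future layers must always be standardized with the recent layer's
#' record so that projected change is expressed on the fitted scale.
#'
#' @param values numeric matrix or data frame, rows = sites/individuals,
#'   columns = variables.
#' @param ids row identifiers (site or individual ids).
#' @param layer layer label, `"recent"` or `"future:<scenario>"`.
#' @param standardization optional list with numeric vectors `mean` and
#'   `sd` (named by variable) recording an applied standardization.
#' @return An object of class `env_table`.
#' @export
env_table <- function(values, ids = rownames(values), layer = "recent",
                      standardization = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(ids)) ids <- as.character(seq_len(nrow(values)))
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("duplicated site ids in environmental table")
  if (length(ids) != nrow(values)) stop("ids length != number of rows")
  rownames(values) <- ids
  incomplete <- colnames(values)[colSums(is.na(values)) > 0]
  structure(
    list(values = values, ids = ids, layer = layer,
         standardization = standardization, incomplete = incomplete),
    class = "env_table"
  )
}

#' @export
print.env_table <- function(x, ...) {
  cat("env_table [", x$layer, "]: ", nrow(x$values), " sites x ",
      ncol(x$values), " variables\n", sep = "")
  cat("  variables:", paste(colnames(x$values), collapse = ", "), "\n")
  if (length(x$incomplete))
    cat("  incomplete (missing cells):",
        paste(x$incomplete, collapse = ", "), "\n")
  if (!is.null(x$standardization)) cat("  standardized\n")
  invisible(x)
}

#' @export
dim.env_table <- function(x) dim(x$values)

#' Read a wide-format environmental CSV
#'
#' First column is the site id; remaining columns are variables. Variables
#' with any missing cell are flagged (`$incomplete`) so they can be dropped
#' before modelling, as is done for patchily measured lake variables such
#' as total dissolved solids.
#'
#' @param path CSV path.
#' @param layer layer label recorded on the table.
#' @return an [env_table()].
#' @export
load_env <- function(path, layer = "recent") {
  df <- utils::read.csv(path, check.names = FALSE)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop("duplicated site ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  env_table(as.matrix(df[, -1, drop = FALSE]), ids = ids, layer = layer)
}

#' Write an environmental table to CSV
#' @param env an [env_table()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_env <- function(env, path) {
  df <- data.frame(site = env$ids, env$values, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Standardize environmental variables (z-scores)
#'
#' Centers and scales each variable. When `reference` is supplied (the
#' recent layer), its means and standard deviations are used, so a future
#' layer is expressed in recent-layer units. A table that already carries
#' the same standardization record is returned unchanged, making the
#' operation idempotent for a fixed reference.
#'
#' @param env an [env_table()] to standardize.
#' @param reference optional [env_table()] providing the standardization
#'   record (either raw, in which case its own means/SDs are computed, or
#'   already standardized, in which case its stored record is reused).
#' @return a standardized [env_table()] carrying the record used.
#' @export
standardize_env <- function(env, reference = NULL) {
  rec <- if (is.null(reference)) {
    if (!is.null(env$standardization)) return(env)
    list(mean = colMeans(env$values, na.rm = TRUE),
         sd = apply(env$values, 2, stats::sd, na.rm = TRUE))
  } else if (!is.null(reference$standardization)) {
    reference$standardization
  } else {
    list(mean = colMeans(reference$values, na.rm = TRUE),
         sd = apply(reference$values, 2, stats::sd, na.rm = TRUE))
  }
  if (!is.null(env$standardization) && identical(env$standardization, rec))
    return(env)
  vars <- colnames(env$values)
  missing_vars <- setdiff(vars, names(rec$mean))
  if (length(missing_vars))
    stop("reference lacks variables: ", paste(missing_vars, collapse = ", "))
  zero <- vars[rec$sd[vars] == 0 | is.na(rec$sd[vars])]
  if (length(zero))
    stop("zero or undefined SD for variable(s): ",
         paste(zero, collapse = ", "))
  z <- sweep(sweep(env$values, 2, rec$mean[vars], "-"), 2, rec$sd[vars], "/")
  env_table(z, ids = env$ids, layer = env$layer,
            standardization = list(mean = rec$mean[vars], sd = rec$sd[vars]))
}

#' Drop strongly inter-correlated environmental variables
#'
#' Greedy pruning: variables are visited in `keep_priority` order (then
#' original column order); a variable is retained unless its squared
#' Pearson correlation with an already-retained variable exceeds
#' `r2_threshold`, in which case it is dropped and the triggering variable
#' recorded in the drop ledger.
#'
#' @param env an [env_table()].
#' @param r2_threshold squared-correlation threshold above which the later
#'   variable is dropped (default 0.7, strict inequality).
#' @param keep_priority character vector of variables to consider first
#'   (e.g. those of highest biological relevance).
#' @return pruned [env_table()]; the drop ledger is in
#'   `attr(, "dropped")` as a data frame (variable, r2, kept_by).
#' @export
prune_correlated <- function(env, r2_threshold = 0.7, keep_priority = NULL) {
  vars <- colnames(env$values)
  order_vars <- c(intersect(keep_priority %||% character(), vars),
                  setdiff(vars, keep_priority %||% character()))
  r <- stats::cor(env$values, use = "pairwise.complete.obs")
  kept <- character()
  dropped <- data.frame(variable = character(), r2 = numeric(),
                        kept_by = character())
  for (v in order_vars) {
    r2v <- r[v, kept, drop = TRUE]^2
    if (length(kept) && any(r2v > r2_threshold, na.rm = TRUE)) {
      j <- which.max(r2v)
      dropped <- rbind(dropped, data.frame(variable = v, r2 = r2v[j],
                                           kept_by = kept[j]))
    } else {
      kept <- c(kept, v)
    }
  }
  kept <- vars[vars %in% kept]  # restore original column order
  out <- env_table(env$values[, kept, drop = FALSE], ids = env$ids,
                   layer = env$layer,
                   standardization = if (!is.null(env$standardization))
                     lapply(env$standardization, function(p) p[kept]))
  attr(out, "dropped") <- dropped
  out
}

#' Read a long-format environmental grid CSV
#'
#' Expected columns: `cell`, `x`, `y`, `variable`, `layer`, `value`. Each
#' layer becomes an [env_table()] whose ids are cell ids; cell coordinates
#' are attached as `attr(, "coords")`.
#'
#' @param path long-format CSV path.
#' @return named list of [env_table()]s, one per layer.
#' @export
load_env_grid <- function(path) {
  df <- utils::read.csv(path)
  need <- c("cell", "x", "y", "variable", "layer", "value")
  if (!all(need %in% names(df)))
    stop("grid CSV needs columns: ", paste(need, collapse = ", "))
  coords <- unique(df[, c("cell", "x", "y")])
  out <- lapply(split(df, df$layer), function(d) {
    wide <- stats::xtabs(value ~ cell + variable, data = d)
    m <- matrix(as.numeric(wide), nrow = nrow(wide),
                dimnames = dimnames(wide))
    m <- m[match(as.character(coords$cell), rownames(m)), , drop = FALSE]
    tab <- env_table(m, ids = coords$cell, layer = unique(d$layer))
    attr(tab, "coords") <- coords
    tab
  })
  out
}
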
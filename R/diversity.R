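#' Per-individual heterozygosity
#'
#' Proportion of heterozygous sites: the number of loci with dosage 1
#' divided by the number of loci actually genotyped in that individual.
#' Unlike nucleotide diversity this is insensitive to per-population
#' sample size, so it can be compared across individuals and populations.
#' Compute it on the filtered but unimputed matrix: mode imputation fills
#' in majority homozygotes and would bias the proportion downward.
#'
#' @param gm a [genotype_matrix()].
#' @return data frame (`id`, `population`, `ecotype`,
#'   `proportion_heterozygous`, `n_genotyped`).
#' @export
heterozygosity <- function(gm) {
  d <- gm$dosage
  n_geno <- rowSums(!is.na(d))
  if (any(n_geno == 0))
    stop("individual(s) with no genotyped locus: ",
         paste(gm$individuals$id[n_geno == 0], collapse = ", "))
  het <- rowSums(d == 1, na.rm = TRUE) / n_geno
  data.frame(id = gm$individuals$id,
             population = gm$individuals$population,
             ecotype = gm$individuals$ecotype,
             proportion_heterozygous = unname(het),
             n_genotyped = unname(n_geno))
}

## broadcast a site-level env table to individuals via their population
broadcast_env <- function(env, population) {
  idx <- match(population, env$ids)
  if (anyNA(idx))
    stop("populations missing from environmental table: ",
         paste(unique(population[is.na(idx)]), collapse = ", "))
  env$values[idx, , drop = FALSE]
}

#' Mixed-model association between heterozygosity and one variable
#'
#' Random-intercept linear mixed model (fit by REML with
#' \pkg{lme4}): heterozygosity ~ variable + (1 | population), with
#' population-level environmental values broadcast to individuals. The
#' slope is tested three ways. The headline p-value (`p_value`) is the
#' ANOVA F test with Satterthwaite denominator degrees of freedom
#' (\pkg{lmerTest}), which stays calibrated when the predictor varies at
#' the population level (about as many effective observations as
#' populations). A likelihood-ratio test of ML-refit nested models
#' (`p_lrt`) and a Wald test against a normal reference (`p_wald`) are
#' also reported; both run slightly liberal at this design's scale.
#' Variance explained follows the
#' Nakagawa-Schielzeth decomposition: marginal R2 = fixed-effect variance
#' over fixed + random-intercept + residual variance; conditional R2 adds
#' the random-intercept variance to the numerator.
#'
#' @param het a [heterozygosity()] table.
#' @param env an [env_table()] whose rows are populations (or individual
#'   ids matching `het$id`).
#' @param variable variable name to test.
#' @return object of class `lmm_fit` (a one-row data frame with
#'   `variable`, `slope`, `intercept`, `p_value`, `p_lrt`, `p_wald`,
#'   `r2_marginal`, `r2_conditional`, `var_random`, `var_residual`, `n`).
#' @export
fit_env_lmm <- function(het, env, variable) {
  if (!variable %in% colnames(env$values))
    stop("variable '", variable, "' not in environmental table")
  if (length(unique(het$population)) < 3)
    stop("need >= 3 populations to identify the population random effect")
  x <- if (all(het$population %in% env$ids)) {
    broadcast_env(env, het$population)[, variable]
  } else if (all(het$id %in% env$ids)) {
    env$values[match(het$id, env$ids), variable]
  } else stop("env rows match neither populations nor individuals")
  if (stats::sd(x) == 0)
    stop("variable '", variable, "' is constant; slope unidentifiable")
  df <- data.frame(het = het$proportion_heterozygous, x = x,
                   population = factor(het$population))
  fit <- lmerTest::lmer(het ~ x + (1 | population), data = df, REML = TRUE)
  aov_tab <- stats::anova(fit)   # Satterthwaite ddf
  p_sat <- aov_tab[["Pr(>F)"]][1]
  beta <- lme4::fixef(fit)
  vc <- as.data.frame(lme4::VarCorr(fit))
  var_rand <- vc$vcov[vc$grp == "population"]
  var_resid <- vc$vcov[vc$grp == "Residual"]
  var_fixed <- stats::var(stats::model.matrix(fit) %*% beta)[1]
  denom <- var_fixed + var_rand + var_resid
  # likelihood-ratio test on ML refits of the nested pair
  full_ml <- lme4::lmer(het ~ x + (1 | population), data = df, REML = FALSE)
  null_ml <- lme4::lmer(het ~ 1 + (1 | population), data = df, REML = FALSE)
  lrt <- 2 * (stats::logLik(full_ml) - stats::logLik(null_ml))
  p_lrt <- stats::pchisq(as.numeric(lrt), df = 1, lower.tail = FALSE)
  tval <- stats::coef(summary(fit))["x", "t value"]
  p_wald <- 2 * stats::pnorm(-abs(tval))
  out <- data.frame(variable = variable,
                    slope = unname(beta["x"]),
                    intercept = unname(beta["(Intercept)"]),
                    p_value = p_sat, p_lrt = p_lrt, p_wald = p_wald,
                    r2_marginal = var_fixed / denom,
                    r2_conditional = (var_fixed + var_rand) / denom,
                    var_random = var_rand, var_residual = var_resid,
                    n = nrow(df))
  class(out) <- c("lmm_fit", "data.frame")
  out
}

#' Heterozygosity-environment association table
#'
#' One [fit_env_lmm()] row per variable with a significance flag at
#' p < 0.05 (on the Satterthwaite headline p-value), mirroring the layout
#' of a diversity-environment results table.
#'
#' @param het a [heterozygosity()] table.
#' @param env an [env_table()].
#' @param variables variables to test (default: all in `env`).
#' @param alpha significance level for the flag (default 0.05).
#' @return data frame of fits with a `significant` column.
#' @export
association_table <- function(het, env, variables = colnames(env$values),
                              alpha = 0.05) {
  rows <- lapply(variables, function(v) {
    fit <- tryCatch(fit_env_lmm(het, env, v), error = function(e) NULL)
    if (is.null(fit)) {
      data.frame(variable = v, slope = NA_real_, intercept = NA_real_,
                 p_value = NA_real_, p_lrt = NA_real_, p_wald = NA_real_,
                 r2_marginal = NA_real_, r2_conditional = NA_real_,
                 var_random = NA_real_, var_residual = NA_real_,
                 n = nrow(het))
    } else as.data.frame(fit)
  })
  out <- do.call(rbind, rows)
  out$significant <- !is.na(out$p_value) & out$p_value < alpha
  out
}
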
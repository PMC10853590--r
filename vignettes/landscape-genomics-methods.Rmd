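---
title: "Methods: from genotype matrices to genomic offset"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from genotype matrices to genomic offset}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

landgea implements a landscape-genomics workflow for non-model organisms
sampled across an environmental gradient: filter genotype matrices of
sequence (SNP) and structural (SV) variation, relate genome-wide diversity
to environment, detect candidate adaptive loci by constrained ordination,
map adaptive variation across a landscape, and convert projected climate
change into a per-site genomic offset. This vignette explains each model,
its assumptions, the tunable parameters, and the design choices made where
the methodology left room.

## Genotype filtering

Genotypes enter as VCF and live in the package as an individuals x loci
dosage matrix (0/1/2 copies of the alternate allele, `NA` for missing). The
missing sentinel is never conflated with dosage 0. The filters mirror
standard practice for whole-genome population data:

* **Site filter** — drop non-biallelic records and indels, then loci with
  a missing fraction at or above `max_site_missing` (default 0.30; "less
  than 30% missing" is retained).
* **Individual filter** — drop individuals with missing fraction strictly
  greater than `max_ind_missing` (default 0.30).
* **SV support recode** — SV genotypes backed by fewer than
  `min_support = 3` supporting read pairs become missing; the panel is
  then re-filtered with the stricter SV ceiling (`0.20`), reflecting the
  noisier genotyping of structural variation.
* **LD pruning** — within 200-kb windows, the later locus of any pair with
  squared dosage correlation above 0.5 is removed. The scan is greedy and
  left-to-right; windows are anchored at absolute multiples of half the
  window width, which makes pruning independent of which loci were removed
  earlier and therefore idempotent. The window anchoring and scan order
  are conventions of this package: only the threshold and window width are
  prescribed by common usage, and both are exposed.
* **Repeat exclusion** — loci falling in BED intervals (0-based half-open,
  converted to 1-based inclusive) are removed.
* **Imputation** — where downstream methods need complete data (PCA, RDA),
  each missing entry is replaced by the locus's modal dosage; ties break
  to the smaller dosage for determinism. Heterozygosity is always computed
  *before* imputation, because mode imputation injects majority
  homozygotes and would bias heterozygote counts downward.

Every filter appends a record (operation, removed, retained) to the
matrix's provenance log, and input counts always reconcile with output
plus removed.

## Heterozygosity and diversity-environment models

Individual heterozygosity is the number of heterozygous sites divided by
the number of sites genotyped in that individual — insensitive to
population sample size, so comparable across populations. Its relation to
each environmental variable is a random-intercept mixed model

> heterozygosity ~ variable + (1 | population)

fit by REML. Because the predictor is constant within populations, the
effective sample size is the number of populations, not individuals; the
headline p-value is therefore the ANOVA F test with Satterthwaite
denominator degrees of freedom, which stays calibrated at this design
(the package's null Monte Carlo holds the empirical type-I error at
5% ± 2% over 500 replicates). Likelihood-ratio and naive Wald p-values
are reported alongside; both run slightly liberal here. Variance explained
follows the Nakagawa–Schielzeth decomposition; the marginal R²
(fixed-effect share) is the headline and the conditional R² is reported
with it, since "model R²" is ambiguous between the two.

## Ordination: PCA, RDA, partial RDA

The constrained ordination is implemented directly from the SVD rather
than delegated, so its conventions are explicit (an independent
cross-check against vegan's `rda()` is part of the test suite):

* **PCA** — SVD of the centered matrix; eigenvalues are per-axis variances
  (denominator n − 1).
* **RDA** — center responses (optionally unit-scale; default centered
  only, since per-locus scaling of dosages is not clearly standard),
  standardize predictors, fit multivariate least squares, and
  eigen-decompose the fitted values' covariance. R² is constrained over
  total variance; adjusted R² uses the Ezekiel correction.
* **Partial RDA** — responses and predictors are first residualized on
  the conditioning table (with an intercept). Predictors that lie wholly
  in the conditioning span are "absorbed" and reported as such rather
  than raising a collinearity error; genuinely collinear predictors still
  error, naming the offending columns.
* **Variance partitioning** — for named predictor sets, a set's marginal
  contribution is the constrained variance of its partial RDA conditioned
  on all other sets, as a fraction of total response variance. With
  mutually orthogonal centered sets the marginals sum exactly to the
  full-model R²; a set duplicated in another has marginal 0.

Eigenvector signs are fixed (largest-magnitude entry of each axis
positive) so results are identical across BLAS builds. Scores follow the
correlation-biplot convention; outlier detection below uses raw locus
loadings and is invariant to any per-axis rescaling because z-scores are
taken per axis.

## Candidate-locus detection and assignment

The genotype–environment association (GEA) step is a partial RDA of
imputed individual dosages on the standardized environmental variables,
conditioned on the first three PCs of the genotype PCA (population
structure). On each of the first three constrained axes, locus loadings
are standardized per axis and loci with |z| > 3 on any axis are
candidates (two-tailed normal tail probability 0.0027). A locus exceeding
the cutoff on several axes counts once, attributed to its max-|z| axis.
Per-axis (rather than pooled) standardization is used, the cited
convention. Each candidate is assigned the environmental variable with
the largest |Pearson r| against its dosages (site-level values broadcast
to individuals through their population); candidates with r² > 0.5 to
their best variable are "strong". Nearest-gene annotation indexes GFF3
`gene` features only, assigns distance 0 inside a gene, and breaks
equidistant ties toward the lower-coordinate gene.

## Adaptive index

The adaptively enriched RDA refits the ordination on the strong
candidates only, excluding in-lake variables with no projected future
(surface area, pH) and the loci assigned to them, keeping the two
temperature and two precipitation variables. A cell's adaptive index on
an axis is the dot product of the axis's variable scores with the cell's
standardized climate — linear in climate, zero at the mean-climate cell,
and sign-symmetric (flipping an axis flips the map). Grid climate is
standardized with the *sampling-site* recent-layer means and SDs (not the
grid's own), so map values are on the same scale as the sample scores;
which reference the original methodology used is unstated, and this
choice is the one that makes samples and map comparable.

## Gradient forest and genomic offset

The gradient forest is built from scratch because turnover functions
require every split's value and impurity decrease, which packaged random
forests do not expose. Per locus (response = population allele
frequency; an individual-dosage mode exists), a forest of CART regression
trees is fit: bootstrap resampling of sites, `mtry = max(1, floor(p/3))`
predictors per split, variance-reduction criterion, minimum child size 2,
500 trees by default. Out-of-bag R² scores each locus; loci with R² <= 0
are discarded. Each retained locus's impurity decreases are rescaled to
sum to its R², and masses are averaged over retained loci, which makes
each predictor's cumulative mass at +Inf equal exactly its R²-weighted
importance — the turnover function F_p is a non-decreasing step function
from 0 to that importance. The "correlation threshold" (0.5) groups
correlated predictors in the importance report; it does not alter the
masses, a documented approximation to the conditional-importance
machinery of the original formulation.

Genomic offset between current and future climate at a site is the
Euclidean distance between turnover-transformed values,
sqrt(sum_p (F_p(future) − F_p(current))²), computed on the raw predictor
scale (tree splits are order-based, so standardization is irrelevant).
Offsets are reported for bio5 by default — the variable that tops the
R²-weighted importance ranking on the bundled fixtures — and for any
requested predictor list. Because F_p has flat tails outside the sampled
climate range, cells already beyond that range saturate: two sites with
equal warming can have very different offsets if one starts near the hot
edge. For that reason the package's monotonicity check is a
*dose-response* evaluation — a common (landscape-mean) baseline with each
cell's projected Δbio5 applied — under which offset rank-correlates with
|Δbio5| essentially perfectly; across raw landscape cells with varying
baselines the rank correlation is real but weaker. Offsets in turnover
space are a metric: symmetric, zero iff the transformed climates agree,
and obeying the triangle inequality across scenario layers.

Where both reproductive ecotypes (stream/shore) co-occur, allele
frequencies at the strong candidates are recomputed per population x
ecotype group, the forest is refit at group level, and offsets are
reported per group.

## The synthetic-data generator

The generator provides desk-scale data with the statistical structure the
pipeline assumes, plus a truth table for recovery tests. Defaults are the
package's study conditions and are not tuned per test:

* **Landscape** — 10 x 10 grid; six variables (bio5, bio6, bio15, bio16,
  pH, log surface area) with linear gradients plus smooth low-frequency
  noise. Temperature variables run along y, precipitation/lake variables
  along x; per-variable noise keeps same-direction variables correlated
  (r² ~ 0.3–0.7, as real bioclim variables are) without collinearity.
  Future layers add a Δbio5 field under a best-case (rcp26, ~1.2–1.9 °C)
  and worst-case (rcp85, ~3.5–6.2 °C) scenario, warming cooler cells more
  (high-latitude amplification).
* **Populations** — 20 populations of 10 individuals on distinct cells
  spanning the bio5 gradient (sample sizes at the scale of the motivating
  studies, which report totals of ~10/population), three of them as
  co-occurring stream/shore pairs sharing a cell.
* **Neutral loci** — hierarchical Balding–Nichols: lineage frequencies
  drift around the ancestral frequency (4 lineages, F = 0.15, assigned at
  random so history is not confounded with climate), population
  frequencies drift around their lineage (F = 0.05), individual dosages
  are Binomial(2, q). The hierarchy matters: without it the planted
  adaptive loci themselves dominate the leading genotype PCs, and
  conditioning on structure would erase the signal the pipeline is meant
  to find — the opposite of real data, where shared history dominates.
* **Adaptive loci** — q_k = logistic(a + b·z_k) with z_k the standardized
  causal variable at the population's cell, |b| ~ Uniform(2, 3), random
  sign, a = logit of the ancestral frequency. Bounded frequencies and a
  tunable effect size; no drift around the deterministic cline.
* **SV panel** — 500 loci tagged DEL/DUP/INS/INV, higher missingness
  (0.10), and per-genotype Poisson(8) read-support counts so the
  support-recode rule is exercised.

What the generator does *not* emulate: linkage and haplotype structure
(loci are spaced beyond the LD window; the pruning code is exercised by
dedicated correlated fixtures instead), migration and isolation by
distance, genotyping error beyond missingness, and selection on standing
structure. Passing recovery tests therefore demonstrates the pipeline's
arithmetic and its behavior under the stated generative model, not
performance on real genomes.

## Problem sizes and numerical choices

The bundled checks run at 20 populations x 10 individuals, 2,000 neutral
+ 50 adaptive SNPs and a 500-locus SV panel; ordination oracles use 8–24
samples; the mixed-model null calibration uses 500 replicates; gradient
forests use 500 trees over the strong-candidate set. Numerical
tolerances: ordination oracle agreement at 1e-8; absorbed-predictor
threshold at relative residual variance 1e-16; eigenvalues below 1e-12 of
the leading one are treated as null axes. All randomness flows through
explicit integer seeds, and rerunning any stage with the same seed is
byte-identical.

## Known limitations

* RDA axes carry no permutation significance tests (none are used
  downstream).
* The gradient forest uses impurity-decrease importance throughout;
  conditional permutation importance is not implemented.
* Offsets extrapolate with flat turnover tails outside the sampled
  climate range; projected climates far beyond it are compressed.
* The Satterthwaite F test assumes Gaussian residuals; heterozygosity
  proportions near 0 or 1 would call for a GLMM, which is out of scope.
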
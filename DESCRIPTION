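Package: landgea
Title: Landscape Genomics of Sequence and Structural Variation: GEA,
    Adaptive Indices and Genomic Offset
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A reusable landscape-genomics pipeline from filtered genotype
    matrices (SNPs and structural variants) to climate-vulnerability
    predictions. Reads VCF genotypes into dosage matrices and applies
    site/individual/genotype filters, LD pruning and repeat-region
    exclusion; standardizes and prunes environmental tables; relates
    individual heterozygosity to environment with linear mixed models;
    implements PCA, redundancy analysis (RDA), partial RDA and variance
    partitioning from first principles; detects candidate adaptive loci
    from RDA loadings, assigns them to environmental variables and
    annotates nearest genes; projects adaptive indices across
    environmental grids; and fits from-scratch gradient-forest turnover
    functions to compute genomic offset under projected climate change.
    A synthetic-data module generates landscape, environment and genotype
    fixtures with planted adaptive loci so every stage is verifiable at
    desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    lme4,
    lmerTest,
    vcfR,
    GenomicRanges,
    IRanges,
    rtracklayer,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    optparse
Config/testthat/edition: 3
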
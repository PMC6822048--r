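Package: poolscape
Title: Landscape Genetics of Pool-Breeding Amphibians
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for microsatellite landscape genetics of
    metapopulation-structured, pool-breeding amphibians. Covers quality
    control of diploid microsatellite genotypes (completeness and sample-size
    filters, sibling removal, null-allele estimation, Monte Carlo exact tests
    of Hardy-Weinberg proportions and linkage disequilibrium with FDR
    control), per-site diversity (rarefied allelic richness, unbiased
    expected heterozygosity, F_IS), Nei-Chesser G_ST and Meirmans-Hedrick
    G''_ST differentiation with exact G tests, bottleneck testing under the
    two-phase microsatellite mutation model, isolation-by-distance analysis
    (Mantel tests, correlograms, scale-dependent IBD slope profiles with
    bootstrap intervals, and a per-site isolation index from IBD residuals),
    circuit-theory effective resistance on raster landscapes with
    per-feature cost optimization by partial Mantel tests and AICc selection
    of additive resistance models, and site-level multivariate analyses
    (collinearity pruning, multiple regression, distance-based RDA with
    conditioning, and MMRR). A forward-time stepping-stone simulator with
    known landscape effects generates synthetic rasters and genotypes so
    every stage can be exercised and validated end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    Matrix,
    geosphere,
    vegan,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
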
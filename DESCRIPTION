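Package: crossdiv
Title: Cross-Domain Biodiversity Effects in Algal-Bacterial Communities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for factorial phytoplankton diversity
    experiments that manipulate both species and intraspecific (strain)
    richness and measure host-associated bacterial communities. Provides a
    synthetic-data generator with known ground truth, iterated rarefaction
    and effective-number-of-species (ENS) diversity metrics for amplicon
    and carbon-substrate-utilization (CLPP) data, Bray-Curtis
    beta-diversity with permutational multivariate analysis of variance
    (PERMANOVA) and non-metric multidimensional scaling (NMDS), net
    biodiversity effects (NBE) with Loreau-Hector additive partitioning
    into complementarity and selection effects, Kruskal-Wallis/Dunn and
    Spearman screens with multiple-testing control, and piecewise path
    models tested by d-separation with Fisher's C and AICc model
    comparison.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
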
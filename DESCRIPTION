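Package: domdiv
Title: Molecular Diversity of Dissolved Organic Matter from FT-ICR MS Peak Lists
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the molecular diversity of dissolved organic
    matter (DOM) characterised by Fourier transform ion cyclotron resonance
    mass spectrometry (FT-ICR MS). Reads calibrated negative-ion peak lists,
    assigns CHNOSP molecular formulas to [M-H]- masses, computes per-formula
    indices (double bond equivalents, modified aromaticity index, nominal
    oxidation state of carbon, degradation index) and compound categories,
    and quantifies molecular alpha-diversity (richness, Gini-Simpson, Rao
    quadratic entropy) and beta-diversity (Jensen-Shannon divergence of
    binned DBE_AI distributions, Bray-Curtis dissimilarity of normalised
    peak intensities). Includes average-linkage clustering with
    silhouette-based selection of the number of clusters, non-metric
    multidimensional scaling, indicator-formula (IndVal) analysis with
    permutation tests, Mantel tests of distance decay against great-circle
    and environmental distances, and a synthetic lake-survey generator with
    known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan,
    cluster,
    geosphere,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
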
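Package: geaoffset
Title: Genotype-Environment Association, Outlier Scans and Genomic Offset
    for Landscape Genomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for landscape-genomics analyses of clinal SNP panels:
    PLINK PED/MAP and VCF import with quality-control filtering (minor
    allele frequency, missingness, LD pruning, within-population mean
    imputation), diversity and Weir-Cockerham F-statistics, Mantel tests
    of isolation by distance and environment, genotype PCA, three
    environment-association outlier scans (trimmed chi-square F_ST scan,
    principal-component Mahalanobis scan, RDA loading scan) combined into
    a consensus panel, redundancy analysis with partial RDA variance
    partitioning over VIF-pruned environmental predictors and
    forward-selected distance-based Moran eigenvector maps, genomic-offset
    estimation under future-climate scenarios (risk of nonadaptedness from
    bounded allele-frequency predictions, and the RDA adaptive-index
    offset), inverse-distance-weighted surface projection, and a
    deterministic simulator of the generations required to close an
    allele-frequency gap under selection.  A synthetic-panel generator
    reproduces the statistical structure of a clinal conifer SNP study so
    the full pipeline runs self-contained.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    geosphere,
    jsonlite,
    stats,
    utils,
    vegan,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
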
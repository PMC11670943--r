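Package: songDivergence
Title: Quantifying Song Divergence Between and Within Avian Taxa
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantifying divergence of learned birdsong between
    and within closely related taxa from mixed-type acoustic feature tables.
    Implements Gower dissimilarity with pairwise omission of missing cells,
    partitioning-around-medoids clustering with silhouette-based selection of
    the number of clusters, principal component analysis for mixed
    numeric/categorical data with mean/zero imputation, Monte Carlo
    permutation tests comparing within- and between-taxon dissimilarities
    with false discovery rate and Bonferroni adjustment, the joint-CDF
    phenotypic divergence score Delta-p with per-feature Hedge's g, and rank
    correlation of divergence scores against relative mtDNA divergence times.
    A synthetic song-feature generator with structural (syllable-block)
    missingness supports end-to-end testing and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), cluster, withr
Config/testthat/edition: 3
biocViews: Clustering, PrincipalComponent, StatisticalMethod
RoxygenNote: 7.3.3
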
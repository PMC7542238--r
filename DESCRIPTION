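Package: snproi
Title: Three-Stage Association Analysis Between SNPs and Brain Regions of Interest
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a three-stage framework for association analysis
    between single nucleotide polymorphisms (SNPs) and imaging-derived brain
    region-of-interest (ROI) phenotypes. Stage one removes redundant SNPs by
    agglomerative hierarchical clustering of pairwise genotype
    dissimilarities, with cophenetic-correlation diagnostics over a grid of
    distance measures and linkage rules. Stage two selects feature SNPs with
    a group-sparse multi-task regression model (a G2,1 plus l2,1 penalised
    least-squares problem solved by iteratively reweighted least squares),
    where SNP groups come from genes or from linkage-disequilibrium r-squared
    connected components. Stage three predicts each ROI phenotype from the
    selected SNPs with epsilon-insensitive support vector regression.
    Includes six regression error measures, a block-LD synthetic genotype and
    phenotype generator, and an end-to-end pipeline with multi-method
    comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    igraph,
    ape,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    kernlab,
    optparse
Config/testthat/edition: 3
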
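Package: hcdc
Title: Hierarchical Clustering with Size-Dependent Correlation Measures for
    Multi-Phenotype Association Testing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint association analysis of multiple correlated phenotypes with a
    genetic variant via a two-step procedure: phenotypes are first grouped by
    agglomerative hierarchical clustering whose between-cluster similarity is
    the Pearson, multiple, or first canonical correlation coefficient depending
    on the sizes of the two clusters, with the number of clusters chosen by the
    largest drop in dendrogram heights; multivariate association tests (MANOVA
    with Wilks' lambda, the proportional-odds reversed regression likelihood
    ratio test, and the extended-Simes combination of univariate p-values) are
    then applied to the within-cluster mean of the standardized phenotypes.
    Includes the average-linkage clustering competitor, a factor-model
    phenotype simulator with Hardy-Weinberg genotypes, and a Monte Carlo
    harness for type-I-error and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    MASS,
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
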
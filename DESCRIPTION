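Package: oncophylo
Title: Phylogenetic Analysis of Cancer Gene Copy-Number Variation and Life History
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative analysis of tumour-suppressor (TSG) and
    oncogene (OG) copy-number variation against life-history traits across
    species. Ingests COSMIC-style cancer gene classifications, per-species
    gene copy counts from CAFE-style gene trees or ortholog record tables,
    and life-history tables; normalizes copy counts to copies per found
    gene, forms TSG/OG ratios and longevity quotients; and fits
    phylogenetic generalized least squares (PGLS) regressions with Pagel's
    lambda, kappa and delta branch-length transformations, either fixed or
    optimized by maximum likelihood. Includes a synthetic-data generator
    that reproduces the statistical structure of such datasets (Yule trees,
    Brownian traits, birth-death gene copy evolution with whole-genome
    duplication lineages, and the masked TSG/OG-lifespan effect) so the
    full pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
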
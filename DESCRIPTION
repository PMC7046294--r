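Package: ancestrydisp
Title: Genetic-Ancestry Disparity Analysis of Tumor Genomic and Transcriptomic Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for comparing tumor genomic and transcriptomic
    landscapes between genetic-ancestry groups: supervised ancestry inference
    by reference-only principal components and k-nearest-neighbor
    classification with a supervised admixture-fraction estimator; 96-channel
    mutational-signature refitting by non-negative least squares with weight
    discard and cosine-similarity pruning; the weighted genome instability
    index (wGII) from segmented copy number; a margin-preserving permutation
    test for ancestry-differential recurrent focal copy-number alterations;
    propensity-score-adjusted association statistics; a simplified
    negative-binomial Wald differential-expression stage; pre-ranked gene-set
    enrichment (GSEA) and sample-set enrichment (SSEA) with fractional ranks;
    and a long non-coding RNA locus-biotype classification and
    androgen-receptor regulation annotation suite. A synthetic-data module
    generates every input with known ground truth so all stages are testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    pracma,
    Rcpp,
    jsonlite,
    yaml,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR
Config/testthat/edition: 3
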
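Package: clonalshift
Title: Clonal Replacement and Intra-Tumor Heterogeneity Under Neoadjuvant
    Therapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multi-region heterogeneity statistics for somatic variants
    (Hudson's depth-corrected Fst, high-frequency regional statistics HFR and
    tHFR, mutation timing classification), a deme-based spatial simulator of
    tumor growth used to build null distributions of clonal change and to
    infer selection and deme size by approximate Bayesian computation, a
    continuous-time multi-type branching-process model of neoadjuvant
    treatment with four-outcome classification and inference of effective
    resistance aberration rates, and deterministic back-calculation of
    pre-treatment resistant-clone size under exponential growth. Includes a
    synthetic multi-region cancer-cell-fraction data generator with planted
    clone architectures so the whole pipeline is testable without access to
    patient sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    tools,
    utils,
    jsonlite,
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR
Config/testthat/edition: 3
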
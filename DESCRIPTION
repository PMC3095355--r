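Package: duplidate
Title: Dating and Functional Characterization of Gene Duplications from
    Transcript Collections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to detect paralogous gene pairs in a transcript-derived
    protein-coding gene collection, estimate their synonymous divergence (Ks)
    by maximum likelihood under the Goldman-Yang codon model with F3x4
    frequencies (with a Nei-Gojobori counting cross-check), decompose the
    duplication-age distribution into an exponential small-scale-duplication
    component plus up to three Gaussian polyploidy peaks, build gene families
    by single-linkage clustering and date their duplication nodes, fit
    power-law family-size distributions and amplification ratios, test GO-term
    enrichment with ancestor propagation, and quantify expression divergence
    between paralogs from per-library EST counts. Includes a synthetic-data
    generator that produces all pipeline inputs with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
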
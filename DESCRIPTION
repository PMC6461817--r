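Package: plexdiff
Title: Differential Expression and Co-Regulation Analysis of Protein Complexes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Maps quantified protein groups from isobaric-label (TMT)
    proteomics experiments onto a curated protein-complex catalog,
    identifies differentially expressed complexes via per-sample subunit
    mean profiles, and identifies differentially assembled complexes via
    a Fisher z-transformed Spearman co-regulation statistic tested
    against a per-complex resampling null. Includes Storey q-value
    multiple-testing correction, Tukey biweight ratio normalization,
    coverage-based complex filtering with redundancy removal, Fisher
    exact term enrichment, and a synthetic-data generator that plants
    known expression and co-regulation effects for end-to-end
    validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
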
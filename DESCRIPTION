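Package: sedadna
Title: Authentication of Marine Sedimentary Ancient DNA and Hybridisation-Capture Bait Design
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to authenticate marine sedimentary ancient DNA (sedaDNA)
    in metagenomic read sets and to design hybridisation-capture RNA baits.
    Includes a synthetic read simulator with a parametric terminal
    cytosine-deamination damage model, a semi-global aligner with percent
    identity and top-score-fraction filtering, ancient/default read
    classification from terminal damage lesions, per-taxon positional
    misincorporation profiles, extraction-blank-control taxon subtraction,
    the per-sample percent eukaryote sedaDNA damage proxy with two-tailed
    Pearson depth correlations, domain-proportion and capture-enrichment
    accounting, and a bait-design pipeline (N-run masking, padding, 3x
    tiling, redundancy collapse, melting-temperature estimation and
    specificity filtering).
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
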
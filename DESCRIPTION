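Package: barcodeval
Title: Evaluation of DNA Barcode Reference Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for evaluating DNA barcode reference libraries of the kind
    assembled for plant groups with the core barcode markers (matK, rbcL) and
    supplementary nrITS2: per-sequence quality index and linguistic complexity,
    homopolymer screening, pairwise global alignment and uncorrected p-distance,
    per-species barcode-gap analysis (maximum intraspecific versus minimum
    interspecific distance, single marker and multilocus), reference-database
    species discrimination with marker-combination synergy, tree-based
    least-inclusive-clade identification, simple indel coding of alignment gaps,
    and the accompanying statistics (Wilson intervals, Scheffe contrasts,
    Spearman and point-biserial correlation, McNemar tests). Includes a
    synthetic-library generator with analytically known ground truth so every
    stage of the pipeline can be tested without sequence downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
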
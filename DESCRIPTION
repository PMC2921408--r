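Package: ippred
Title: Sequence-Based Prediction of Protein-Protein Interface Residues
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies protein-protein interface residues from sequence
    information alone. Each residue is encoded by an integrative profile: the
    unbiased standard deviation of the elementwise product of its
    alignment-derived 20-value sequence profile with the Kyte-Doolittle
    hydropathy scale, spread over a sliding window by Gaussian influence
    coefficients. An ensemble of support vector machines is trained on
    non-overlapping, delta-ASA-ordered balanced subsets of interface and
    non-interface residues, optionally gated by a modified self-organizing map
    that prunes low-population and high-entropy clusters, and member votes are
    combined by an integer threshold. Includes chain-level cross-validation,
    a six-measure evaluation suite (sensitivity, specificity, accuracy,
    precision, F-measure, Matthews correlation coefficient), amino-acid
    interface propensities, and a seeded synthetic fixture generator so the
    whole pipeline is testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    e1071,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
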
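Package: chidt
Title: Succinylation Site Prediction with Chi-Square Difference-Table
    Encoding and a Chi-Square Decision-Table Classifier
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts lysine succinylation sites from protein sequences.
    Fixed-length residue windows centred on candidate lysines are encoded
    with positional scores from a chi-square statistical difference table,
    amino-acid composition and undirected pair-coupled amino-acid
    composition. Per-position 2x20 contingency tables are compressed by
    greedy column merging gated by local chi-square tests; features are
    selected by a forward search that uses a chi-square-terminated maximal
    information coefficient as a unified relevance and redundancy measure
    with redundancy sharing; classification uses a cost-weighted decision
    table with an incremental chi-square decision rule suited to heavily
    imbalanced training sets. Includes a seeded synthetic-data generator,
    evaluation indices (sensitivity, specificity, Matthews correlation,
    Q9), model serialization and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
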
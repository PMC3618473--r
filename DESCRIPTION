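Package: coevent
Title: Combinatorial Genomic Biomarkers of Drug Response in Cancer Cell-Line Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discovering combinatorial genomic biomarkers of drug
    response in cancer cell-line panels. Builds binary genomic-event matrices
    from gene-level mutation and total copy-number tables, partitions screened
    cell lines into sensitive and resistant groups per drug by locating the
    inflection point of the rank-ordered growth-inhibition curve, contrasts
    observed pairwise and triple event co-occurrence with an independence
    model to classify co-selected, partially exclusive and mutually exclusive
    event tuples, scores single- and co-event associations with drug
    sensitivity under fold-change and prevalence filters, cross-validates
    biomarkers by lineage subtraction, and clusters scaled response profiles.
    A synthetic-panel generator with planted marginals, pairwise couplings,
    lineage enrichment and drug effects provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    pracma
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
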
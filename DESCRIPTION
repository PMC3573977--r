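Package: refrank
Title: Reference-Protein Identification and Plurality Rating for
    Homology-Based Annotation Transfer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies experimentally characterized or curated homologs
    ("reference proteins") of a query protein in a local annotated sequence
    collection, evaluates each candidate's homologous relationship by
    cluster-aware reciprocal best hits and a multiple-sequence-comparison
    (MSC) filtered-hit-ratio procedure, and ranks candidates on a 1-6
    plurality rating scale combining reciprocal-search, MSC, pairwise-identity
    and reference-status evidence. Ships a deterministic synthetic multi-genome
    fixture generator and a benchmark harness computing coverage and
    family/subgroup accuracy at rating-score cutoffs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    methods,
    stats,
    utils
Suggests:
    optparse,
    jsonlite,
    yaml,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
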
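Package: kinclass
Title: Draft Kinome Annotation by Profile Search and Top-Hit Consensus
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies members of the eukaryotic protein kinase (ePK)
    superfamily in a predicted proteome and classifies them into the
    hierarchical group/family/subfamily vocabulary of Hanks and Hunter.
    Identification combines a position-specific profile built from a
    kinase-domain alignment, a functional-residue scoring matrix in which
    viable residues are weighted inversely to column variability, and a
    rescue step that recovers conserved unusual kinases and protein
    kinase-like atypical kinases through similarity to a curated reference
    kinome database.  Classification is by consensus of consecutive top
    similarity hits, with partial (group or group/family) classification
    when deeper consensus fails and a conservative tyrosine-kinase policy
    for non-metazoan input.  The package also provides the draft-kinome
    reports (summary, missing core kinases, phylogenetic profile, gene
    product names), a confusion/ROC calculus for scoring a draft kinome
    against a curated truth set at identification, partial and full
    classification levels, and a deterministic synthetic-data generator
    with planted truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
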
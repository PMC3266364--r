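Package: methrelex
Title: Gene Methylation-Cancer Relation Extraction from Biomedical Text
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A hybrid text-mining pipeline that extracts gene
    methylation-cancer associations from PubMed-style abstracts.  It
    combines rule- and dictionary-based named entity recognition (a
    methylation regex, a cancer dictionary with three surface patterns,
    and a gene dictionary with orthographic variant expansion), expansion
    of multi-entity sentences into single-pair relation instances, a rich
    binary feature set (inter-entity n-grams, surrounding words, shallow
    chunks, parse paths, sentence position and alignment-induced
    templates), two maximum-entropy relation classifiers (gene-methylation
    and gene-cancer), and probability-based ranking of gene-cancer
    associations over their evidence sentences.  A deterministic
    synthetic-corpus generator with controllable relational signal makes
    every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Matrix,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    glmnet
Config/testthat/edition: 3
RoxygenNote: 7.3.3
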
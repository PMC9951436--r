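Package: codonopt
Title: Tissue-Specific Codon Optimality Signatures and Probabilistic Codon Optimization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives per-tissue codon-optimality signatures from paired
    protein and mRNA abundance matrices via protein-to-mRNA (PTR) ratios and
    balanced random-forest classification of high-PTR versus low-PTR genes,
    and uses those signatures in a probabilistic codon optimizer that
    generates pools of synonymous coding sequences for a target tissue and
    ranks them by standard gene-design metrics (CAI, codon pair bias,
    effective number of codons, GC content, and a minimum-free-energy style
    folding score). Includes seeded synthetic-data generators for coding
    sequences with planted codon biases and for paired expression matrices
    with tissue-specific PTR structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    randomForest,
    jsonlite,
    Rcpp,
    graphics,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
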
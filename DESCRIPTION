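Package: sigregulon
Title: Defining Overlapping ECF Sigma-Factor Regulons from dRNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for delineating extracytoplasmic-function (ECF) sigma
    factor regulons in Corynebacterium and related Actinobacteria from
    stranded RNA-seq data. The package stages an anti-sigma deletion
    differential-expression analysis (median-of-ratios normalization,
    M/A values, negative-binomial Wald tests, Benjamini-Hochberg
    adjustment), calls transcription start sites from primary 5'-end
    read-start profiles with a 10x enrichment rule, matches bipartite
    -35/-10 stress promoters (GGAAC/GGAAT pentamer, spacer, GTT trimer)
    under spacer constraints, classifies promoters as dual sigmaH/sigmaE
    versus exclusively sigmaH using the base at position -31, derives
    GTT-anchored position-frequency consensus sequences, and scans
    upstream regions of orthologous genes across species for conserved
    stress promoters. A fully specified synthetic-data generator with
    ground truth makes every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Biostrings,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2,
    jsonlite
Config/testthat/edition: 3
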
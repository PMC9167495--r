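Package: ctldcpevo
Title: Domain Evolution Analysis of Group XIV C-Type Lectin
    Domain-Containing Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying the modular domain architecture and
    molecular evolution of the group XIV C-type lectin domain-containing
    proteins (CD93, Clec14A, CD248, Thrombomodulin) and their relatives.
    Classifies EGF-like repeats into subtypes from PROSITE-style sequence
    signatures, derives the extracellular region partition (C-type lectin
    domain, sushi-like region, EGF repeats, mucin-like region,
    transmembrane segment, cytoplasmic tail) from anchor domain
    annotations, estimates per-domain Ka/Ks from codon alignments with
    Nei-Gojobori (1986) and Yang-Nielsen (2000) style counting methods,
    compares conserved synteny blocks between chromosomes and classifies
    gene-absence mechanisms, computes phospho-site consensus logo
    matrices, and simulates domain-structured coding sequences, codon
    evolution with per-region selective pressure, and gene-order
    histories so that every stage can be exercised on data with known
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
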
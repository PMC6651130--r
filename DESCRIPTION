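Package: resistomir
Title: Discovery and Evolutionary Analysis of NB-LRR-Targeting Plant miRNAs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for discovering and characterizing microRNAs that
    regulate NB-LRR disease-resistance genes in plants. Implements antisense
    duplex penalty scoring for target prediction, perfect-match genome locus
    mapping with hairpin minimum-free-energy precursor validation, degradome
    (PARE) cleavage-site classification into T-plot categories 0-4 with a
    rank-based p-value, 21-nt phased siRNA (phasiRNA) cluster detection by
    phase score, TPM normalization with stress-response calling, lightweight
    NB/LRR/CC domain annotation, and Dollo-style birth/death reconstruction
    of miRNA families on dated species trees. A seeded synthetic-study
    generator with a ground-truth manifest makes every stage testable
    end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    ape,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
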
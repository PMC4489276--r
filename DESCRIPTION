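Package: intercov
Title: Interprotein Covariation from TaxID-Paired Multiple Sequence Alignments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds concatenated multiple sequence alignments for two to six
    proteins by pairing homologs that share an NCBI taxonomic identifier,
    scores intra- and interprotein residue covariation with three method
    families (corrected mutual information with average product correction
    and shuffle-null z-scores; mean-field direct coupling analysis scored by
    direct information; pseudo-likelihood Potts model fits scored by
    APC-corrected Frobenius norms), compares and overlaps method rankings,
    and evaluates predictions against structural contact maps at a C-alpha
    distance threshold. Includes seeded generators for planted-coupling
    Potts alignments, homolog hit tables and toy structures, plus circos and
    score-matrix figures exported as SVG.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    bio3d,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
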
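Package: truncguide
Title: Design and Evaluation of Truncated CRISPR-Cas9 Guide RNAs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing full-length (20 nt) and truncated (17 nt)
    SpCas9 single guide RNAs. Enumerates NGG protospacers and designs
    guide pairs under 5'-G rules with cloning oligo templates, profiles
    candidate off-target sites by Hamming mismatches over the full and
    PAM-proximal 17 nt windows, calls indels from Sanger-style clone
    sequences with an affine-gap global aligner and classifies reading
    frames, converts T7 endonuclease I band intensities to indel
    percentages, summarises GFP-reporter knockout efficiencies with
    paired tests, and simulates all of these inputs with known ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
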
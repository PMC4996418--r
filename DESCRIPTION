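Package: twistmotif
Title: Signature-Motif Discovery and Paralog Classification for the
    Twist bHLH Family
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for comparative analysis of two-paralog protein
    families, developed around the vertebrate Twist1/Twist2 pair.
    Implements PROSITE-format motif construction from alignment column
    profiles, discriminative end-trimming refinement of signature
    motifs, key-residue paralog classification, kinase-consensus
    phosphosite scanning, glycine-rich region detection and subtyping,
    alignment trimming, substitution-matrix distances, neighbor-joining
    trees with bootstrap support, classical metric multidimensional
    scaling of sequence space, evolutionary-trace residue classing, and
    a seeded simulator of Twist-like duplicated families with planted
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    S4Vectors,
    ape
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
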
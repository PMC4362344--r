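Package: HolobiontEST
Title: Holobiont EST Annotation, Partitioning and C-Type Lectin Domain Mining
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for expressed sequence tag (EST) surveys of
    planktonic holobionts (a rhizarian host together with its photosymbionts
    and associated microbes). Cleans assembled unigenes, partitions them into
    ribosomal and putative messenger RNA by a keyword/identity/length rule,
    assigns taxonomy by lowest-common-ancestor binning of similarity hits,
    clusters six-frame translations across samples at 50% identity, profiles
    GC content, and mines c-type lectin domains (four conserved cysteines
    plus a WIGL-like motif) with sugar-binding motif classification and a
    neighbor-joining protein phylogeny. Ships a synthetic holobiont EST
    generator with full ground truth so every stage is testable without
    large sequencing archives.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    Rcpp,
    Biostrings,
    ape,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
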
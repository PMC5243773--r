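Package: sargtype
Title: Comparative Mitogenomics and Molecular Typing of Holopelagic Sargassum
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing the collinear mitochondrial genomes of the
    three holopelagic Sargassum forms (S. fluitans III, S. natans I and
    S. natans VIII): whole-genome fixed-difference scanning, codon-aware
    variant effect annotation, in-silico PCR with the diagnostic cox2/cox3
    primer panel, amplicon-based typing of specimens into forms, and a
    distance-based (neighbour-joining, bootstrap) phylogeny. Ships a
    transcription of the published 98-site variant panel and a
    constraint-solving simulator that builds synthetic reference mitogenomes
    realizing that panel exactly, together with labeled Sanger-style amplicon
    cohorts for validating the typing assay end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    jsonlite,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
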
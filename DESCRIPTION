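Package: ribomotifs
Title: Tertiary Motif Annotation and Sequence Conservation Analysis for
    Riboswitch Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Geometric annotation of RNA tertiary structure: hydrogen-bond
    and base-pair detection with Leontis-Westhof style edge classification,
    extraction of a nested secondary-structure skeleton with P/L/J element
    labels, and detectors for seven classes of tertiary motifs (base
    triples and quadruples, A-minor and G-minor interactions, ribose
    zippers, pseudoknots, kissing loops, kink-turns and loop-receptor
    interactions). Alignment columns of Stockholm files are profiled for
    conservation with a strict greater-than-95 percent rule, structure
    residues are mapped onto alignment columns by pairwise insertion, and
    motifs are classified by how conserved their positions are. A census
    pipeline orchestrates the survey over a set of riboswitch aptamer
    structures and summarises motif counts, base-triple compositions and
    A-minor type and receptor statistics. A synthetic-geometry generator
    builds idealised nucleotides, base pairs, helices and planted motifs
    so every detector is testable without structure downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    bio3d,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
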
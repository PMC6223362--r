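Package: spatwin
Title: 3D Sliding-Window Analysis of Sequence Data on Protein Structures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps sequence-aligned data (nucleotide or protein multiple
    sequence alignments, or per-residue numeric tables) onto protein
    structures and applies a three-dimensional sliding window: for each
    residue, all residues within a user-defined radius are collected, the
    data attached to them is aggregated, and a scoring function (Tajima's D,
    nucleotide diversity, Watterson's theta, segregating sites, Shannon
    entropy, or a user-supplied function) is evaluated and mapped back to
    the central residue. Results are exported as TSV, JSON, or as a PDB file
    with scores written into the B-factor column for structure-viewer
    coloring. Nucleotide alignments are mapped codon-wise onto structure
    residues, including reverse-sense translation, so population-genetic
    statistics can be computed over spatially linked codons. Includes a
    deterministic synthetic-data generator (toy structures and alignments
    with known statistical structure) used throughout the tests and
    documentation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    methods,
    optparse,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
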
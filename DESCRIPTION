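Package: cofsig
Title: Ligand-Contact Signature Motifs for Cofactor-Dependent Protein Discovery
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Discovers spaced sequence signatures that mark functional
    cofactor-binding proteins, with the cobalamin-dependent photoreceptor
    family as the reference application. Given a ligand-bound reference
    structure and homologous query sequences, the package classifies
    queries by structural similarity (Kabsch superposition and a C-alpha
    RMSD filter) and phylogenetic placement, sizes docking boxes from the
    ligand radius of gyration, detects ligand-contact residues including
    the lower axial metal ligand, intersects contacts with alignment
    conservation to derive a spaced signature motif, and mines sequence
    databases for signature-bearing candidates with greedy identity
    clustering and sequence-similarity-network export. Synthetic-data
    generators and brute-force reference implementations make every stage
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    bio3d,
    Biostrings,
    ape,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    xml2
Config/testthat/edition: 3
biocViews: Software, StructuralPrediction, SequenceMatching, Alignment,
    Phylogenetics, MotifDiscovery
RoxygenNote: 7.3.3
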
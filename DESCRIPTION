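Package: septG
Title: Septin G-Interface Contact Mapping, Motif Annotation and Nucleotide
    Occupancy Modelling
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing the septin G dimerization interface from
    macromolecular structures and sequences: geometric hydrogen-bond and
    proximity-contact detection between chains and around bound guanine
    nucleotides, van der Waals clash checks, annotation of residues to the
    canonical GTPase motifs (G1-G5, trans loop 1, alpha-4, Sep4/beta-meander
    with WG-relative offsets), region-by-region interface fingerprints and
    differential-contact comparison between structures, Kabsch superposition
    with per-residue displacements, pairwise identity / marker covariation /
    neighbor-joining tree analyses keyed to the catalytic threonine, and a
    hetero-oligomer nucleotide-occupancy model linking per-subunit GTP-bound
    fractions to bulk GDP:GTP ratios. Includes seeded synthetic-data
    generators with machine-checkable ground truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    tools,
    utils,
    bio3d,
    Biostrings,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
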
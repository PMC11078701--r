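Package: pascreen
Title: PAS-Domain Recognition and Dimer-Orientation Screening for Sensor
    Histidine Kinases
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Structural-bioinformatics toolkit for classifying the dimer
    architecture of periplasmic PAS sensor domains of bacterial histidine
    kinases. Reads PDB/mmCIF structures, assigns secondary structure from
    backbone hydrogen-bond energetics, recognizes the PAS fold (five-stranded
    antiparallel beta-sheet in 2-5-1-4-3 spatial order flanked by three
    helices), detects helix N-cap motifs in structures and in multiple
    sequence alignments, quantifies interface and crystal-contact burial by
    solvent-accessible surface area with crystallographic symmetry expansion,
    and classifies chain pairs as alpha1-interface or alpha3-interface
    parallel dimers. Includes a deterministic generator of ground-truth
    labeled synthetic PAS monomers, dimers and alignments for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
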
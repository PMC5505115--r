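Package: metaspec
Title: Spectral-Network Assembly and Gapped De Novo Sequencing for
    Multi-Protease, Multi-Dissociation Proteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A desk-scale pipeline for de novo protein sequencing from
    tandem mass spectra of overlapping peptides. Spectra acquired with
    complementary dissociation modes (CID, HCD, ETD) from the same
    precursor are converted to scored prefix-residue-mass (PRM) spectra
    and merged; merged PRM spectra from peptides with overlapping
    sequences (different proteases, missed cleavages) are aligned into a
    spectral network; network alignments are integrated by A-Bruijn
    gluing into contigs whose consensus spectra (meta-contigs) are read
    out as gapped de novo sequences and mapped onto a protein database
    with a mass-tolerant aligner and maximum-parsimony protein
    inference. Includes a synthetic-acquisition module that emulates a
    venom-proteomics experimental design (10 kDa fractionation, four
    proteolytic digests, data-dependent CID/HCD/ETD triples) with full
    ground truth, so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    knitr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
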
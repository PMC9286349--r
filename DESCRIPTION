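Package: SpliceBench
Title: Benchmarking Cis-Spliced Peptide Identification in HLA-I Immunopeptidomics
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for benchmarking database-search strategies for the
    identification of proteasome-generated spliced peptides in HLA class I
    immunopeptidomes. Implements peptide-to-proteome splice mapping with the
    non-spliced > cis > trans explanation hierarchy, construction of ground-truth
    reference databases in which each target peptide is identifiable only as its
    assigned category, the AP and MBS de novo candidate selection workflows for
    spliced-peptide target database generation, a fragment-matching stand-in
    search engine with target-decoy false discovery rate estimation, seeded
    synthetic data generators (proteomes, immunopeptidome peptide sets, MS2
    spectra, de novo candidate tables), and precision/recall benchmarking of
    peptide-spectrum match sets against answer keys.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    stringi,
    withr,
    BiocGenerics,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Proteomics, MassSpectrometry, ImmunoOncology, Software
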
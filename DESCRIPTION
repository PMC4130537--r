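Package: somaticRS
Title: Replacement/Silent Somatic Mutation Analysis and Interface Metrics for
    Antibody Variable Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Codon-aware classification of somatic mutations in antibody
    variable-region genes against their germline precursor (replacement vs
    silent, transition vs transversion, Kabat region), region-stratified
    contingency statistics (Mantel-Haenszel common odds ratio, the
    Cochran-Mantel-Haenszel test and the Breslow-Day homogeneity test, with
    each antibody as a stratum), the inherent R/S ratio of a sequence by
    exhaustive single-substitution enumeration, and structure-analysis
    operators for antibody-ligand complexes: Van der Waals contacts,
    intermolecular hydrogen bonds, electrostatic/Van der Waals interaction
    energy decomposition, RMSD/RMSF, and Ramachandran phi/psi coding of
    CDR-H3 take-off geometry. Includes a seeded synthetic-data generator
    (germline/clone pairs with planted, labelled mutations; toy complexes
    and trajectories with known geometry) so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    bio3d,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    seqinr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
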
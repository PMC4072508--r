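Package: bh3scan
Title: Structure- and Data-Based Discovery of BH3-Like Peptides in Proteomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Derives interface statistical potentials (Calpha/Cbeta and
    all-heavy-atom receptor variants) from a receptor-peptide template
    complex and a database of single-chain structures, builds
    position-specific scoring models from peptide SPOT-array intensities,
    and scans proteomes for candidate BH3 motifs on the heptad register
    using compositional and conservation filters with genomic Z-score
    normalisation. Includes SPOT-array negative-control classification,
    affinity and specificity benchmarking by ROC/AUC with bootstrap
    confidence intervals, and seeded generators for synthetic structures,
    structure databases, proteomes, SPOT tables, alignments and
    dissociation-constant tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: StructuralBioinformatics, Proteomics, MotifDiscovery
RoxygenNote: 7.3.3
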
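Package: oligoscope
Title: Integrative Mass-Spectrometry Analysis of Lipidated-Peptide Oligomerization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dissecting the self-association of lipid-conjugated
    therapeutic peptides (liraglutide as the built-in analyte) by native mass
    spectrometry. Covers exact mass bookkeeping for modified peptides, peak
    picking and oligomer-state assignment from charge-state series, single-ion
    charge inference from accumulated-intensity slopes (STORI / direct mass
    technology) with mass-domain region segmentation, electron-capture
    dissociation c/z fragment-ladder annotation with differential coverage
    analysis, and a coarse-grained self-assembly simulator with cluster,
    hydrophobic-core, and interaction-pair trajectory analytics. Seeded
    synthetic-data generators emulate every input the pipeline consumes.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    deSolve,
    jsonlite,
    yaml,
    igraph
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
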
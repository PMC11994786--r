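Package: RITEproteomics
Title: Dual-Tag AP-MS Interactome Analysis for Recombination-Induced Tag
    Exchange Mouse Models
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for affinity-purification mass spectrometry
    (AP-MS) experiments built on Cre/lox tag-switch (RITE) knock-in alleles,
    where a 3xHA epitope tag is exchanged for a V5 tag in Cre-expressing
    cells. Provides protein quantification by the pairwise-ratio method
    (geometric median of cross-pair peptide ratios) with presence/absence
    evaluation and ratio capping, a three-negative-control significance
    purge that defines per-tag interactomes, cross-tag interactome
    comparison (tag specificity, annotation-category tallies, overlap with
    reference interactor lists), a synthetic peptide-level data generator
    with spiked interactor classes for end-to-end validation, and an
    in-silico model of the loxP-3xHA-loxP-V5 donor cassette (lox site
    detection, Cre excision, epitope translation, genotyping amplicon and
    restriction-fragment arithmetic).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    data.table,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
biocViews: Proteomics, MassSpectrometry, Software
RoxygenNote: 7.3.3
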
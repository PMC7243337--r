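Package: telochec
Title: Chromatin Organization at Yeast Subtelomere-Telomere Junctions from
    In Vivo ChEC Footprinting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools to infer chromatin organization at Saccharomyces
    cerevisiae subtelomere-telomere junctions from in vivo ChEC (Chromatin
    Endogenous Cleavage) partial-digestion footprints read out by indirect
    end-labeling. The package encodes the analyzed restriction fragments as
    coordinate-annotated templates with ground-truth protein occupancy,
    provides a forward simulator of calcium-induced MNase-fusion digestion
    time courses, renders fragment populations to virtual Southern-blot
    lane profiles, detects bands and converts them to cut-site offsets,
    consolidates preferential MNase-sensitive sites across constructs and
    time points, classifies inter-site intervals with the 146-bp
    nucleosome-footprint rule, annotates protein-binding sites by
    position-weight-matrix scanning with exact dynamic-programming
    p-values, computes junction accessibility ratios, reconstructs
    chromatin models, and discriminates direct Rap1 binding from a
    cis-telomere fold-back by an in-silico genotype/context experiment.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    GenomeInfoDb,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'gel.R'
    'caller.R'
    'templates.R'
    'chec-sim.R'
    'inference.R'
    'pipeline.R'
    'pwm.R'
    'telochec-package.R'
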
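Package: perichrom
Title: Peripheral Chromatin Analysis with DamID and Hi-C
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for studying nuclear-pore-anchored peripheral
    chromatin. Calls lamina-associated domains and nucleoporin binding sites
    from binned DamID-seq counts with a Gaussian hidden Markov model,
    classifies sites against nuclear pore complex (NPC) and nucleoplasmic
    reference sets with permutation enrichment tests, computes Hi-C
    compaction statistics (iterative correction, observed/expected maps,
    Armatus-style TAD calling, average contact frequency, modified insulation
    score, compartment eigenvectors and saddle plots, anchor pileups),
    aggregates signal/metagene/AT-content profiles around sites, and provides
    nuclear-geometry statistics for FISH radial distances and diameter
    intensity profiles. Includes seeded synthetic-data generators that emulate
    each input so the full workflow runs end-to-end at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
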
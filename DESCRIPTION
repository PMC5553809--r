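Package: ChIPratio
Title: Ratio-Based ChIP-Seq Occupancy Analysis for Bacterial Nucleoid Proteins
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for mapping the genomic occupancy of abundant bacterial
    nucleoid-associated proteins from ChIP-seq read libraries. Implements
    exact-match, strand-collapsed read anchoring onto a circular genome,
    trimmed-mean scaling normalization, running-window enrichment-ratio (R)
    tracks, ratio-threshold peak and unbound-region calling with replicate
    combination, a direct/inverted repeat-pair scanner over configurable arm
    and spacer ranges, and observed-versus-expected base-pair overlap
    statistics (K) between repeat catalogs or external interval sets and the
    called occupancy regions. A synthetic-data module simulates control and
    immunoprecipitated libraries with planted binding sites, planted repeat
    pairs and an origin-proximal copy-number gradient so the whole pipeline
    can be exercised against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
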
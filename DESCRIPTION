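Package: polypDE
Title: Differential Expression Between Polyp Types of a Colonial Hydrozoan
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pair-aware RNA-seq differential-expression pipeline for
    polymorphic hydrozoan colonies with three polyp types (gastrozooid,
    gonozooid, dactylozooid). Counts paired-end fragments whose two mates
    map to the same transcript, normalizes libraries by median-of-ratios
    size factors, tests transcripts with a negative-binomial exact test
    under two dispersion engines (a conservative maximum-of-trend engine
    and a likelihood-shrinkage engine), removes heterogametic (male versus
    female gonozooid) confounding by a staged two-branch workflow that
    rescues putative maternal transcripts, calls polyp-specific transcripts
    by a consensus rule across comparisons and engines, and provides
    library-distance, MA-plot and dispersion-trend diagnostics. Includes a
    synthetic-data generator with ground-truth effect classes for
    benchmarking, and assembly length statistics (minimum-length filter,
    N50, size histogram).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    jsonlite,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    edgeR
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
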
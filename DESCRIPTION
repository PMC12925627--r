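Package: cenevo
Title: Point-Centromere Annotation and Centromere-Transition Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Annotates short motif-defined centromeres in fungal genome
    assemblies and simulates how new centromere variants spread. Implements
    position-weight-matrix construction from aligned sites, log-odds scanning
    with exact p-value calibration by dynamic programming, a two-stage
    CDEI/CDEII/CDEIII point-centromere annotation pipeline with a rule-based
    filter cascade and karyotype inference, a single-motif core-centromere
    annotator for Mucoromycota-style centromeres based on downstream GC
    profiling, drift-selection centromere-transition simulators (haploid,
    diploid, and diploid populations with an optional meiosis step) validated
    against exact Markov-chain oracles, and a synthetic-genome generator that
    plants centromeres with known truth so the whole toolkit is testable
    without external assemblies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    methods,
    rtracklayer,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
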
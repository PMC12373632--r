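Package: splicesim
Title: Splice-Aware Simulation of Smart-seq3 Single-Cell Sequencing Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates realistic paired-end Smart-seq3 single-cell RNA
    sequencing reads with full ground-truth traceability. Learns empirical
    protocol characteristics (fragment lengths for UMI-containing and
    internal reads, reads per UMI, internal-to-UMI read ratios, unspliced
    RNA fractions, positional quality scores) from a tagged BAM file,
    builds a user-controllable ground truth of annotated and novel
    isoforms with per-population percent-spliced-in and unspliced
    fractions, and emits paired FASTQ reads that mimic the Smart-seq3
    library preparation workflow: tagmentation tagging, PCR amplification,
    5' UMI-fragment and internal-fragment extraction, strand rules,
    substitution errors, subsampling, and empirical quality assignment.
    Includes a synthetic-fixture generator (toy genome, annotation,
    tagged BAM, parametric default characteristics) so the full pipeline
    runs without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    jsonlite,
    methods,
    optparse,
    rtracklayer,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
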
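Package: permpeaks
Title: Strand-Aware ChIP-Seq Peak Detection with Permutation-Based FDR
    Control
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Statistical detection of protein-bound genomic regions from
    mapped ChIP-seq reads.  Reads are virtually extended to the average
    sequenced-fragment length and piled up per strand; taking the
    per-position minimum across strands makes calls robust to PCR
    duplicate artifacts, which inflate coverage on a single strand only.
    Immunoprecipitation (IP) coverage is scaled to a common sequencing
    depth and moment-matched to the control coverage distribution, a
    per-nucleotide enrichment score is computed by a ratio (default) or
    Poisson upper-tail test with a background floor on the control, and
    candidate regions above a score cutoff are merged and tested for
    significance against a null distribution obtained by randomly
    permuting sample labels over the pooled reads, yielding a score
    threshold that controls the false discovery rate.  Includes readers
    for common mapped-read table dialects, UCSC wiggle and BED export,
    duplicate-read QC, gene-proximity annotation, and a synthetic
    ChIP-seq simulator with planted peaks and PCR-duplicate injection
    for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    IRanges,
    rtracklayer,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
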
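Package: chromdens
Title: Chromosome-Scale Feature Density Maps from Genome Annotation
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes the density of genomic features (genes, exons,
    repeats, GC content, ...) in non-overlapping tiling windows along
    whole chromosomes, directly from GFF2/GFF2.5/GFF3 annotation files,
    and renders the result as a configurable multi-track,
    multi-chromosome SVG heat-strip figure together with a tabular
    density file. Overlapping feature intervals are merged per strand
    track (minus, plus, or both strands fused) before coverage is
    measured, so a density is the percentage of window bases covered by
    at least one feature of a type. Includes a catalog of numbered
    colour scales, a deterministic SVG layout engine, a command-line
    interface, and a seeded synthetic-annotation generator for testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    IRanges,
    Biostrings,
    grDevices,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
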
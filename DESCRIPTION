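Package: chdipmeta
Title: Metagene and Exon-Intron Composite Profiling for ChDIP-chip Tiling Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for genome-wide histone-modification maps from
    two-channel tiling arrays, built around the budding-yeast H2B
    monoubiquitylation (H2BK123ub1) ChDIP-chip design. Raw per-probe IP and
    control intensities from replicate arrays are turned into a quantile
    normalized, replicate-averaged log2(IP/control) signal track; genes and
    their flanking intergenic regions are scaled to a fixed bin layout and
    averaged into strand-aware composite ("averaged gene") profiles,
    optionally stratified by transcription rate or coding-region length;
    intron-containing genes are profiled on an exon1-intron-exon2 axis; and
    per-bp nucleosome occupancy is summarised by length-weighted segment
    averages. A synthetic-data generator emulates the tiling-array study
    design with planted enrichment structure so that every stage can be
    validated against a known ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
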
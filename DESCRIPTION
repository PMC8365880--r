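Package: enhancerscape
Title: Enhancer Landscape Analysis for Tumor Versus Normal ChIP-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for active-enhancer landscape analysis from
    histone-mark ChIP-seq (H3K27ac, H3K4me1) and RNA-seq in paired
    tumor/normal designs. Calls typical and super enhancers from distal
    peaks by 12.5 kb stitching and the rank-curve tangent-slope-1 cutoff,
    identifies gain and lost variant enhancer loci (VELs) and variant super
    enhancer loci (VSELs) by tumor/normal H3K27ac fold change, calls
    differentially expressed genes from count matrices, assigns proximal
    genes and intersects VELs, DEGs and transcription-factor target sets,
    and ranks known motifs (position weight matrices) by enrichment in
    gain-VEL sequences. Ships a synthetic-data generator that plants
    ground-truth enhancers, expression changes and motif instances on a toy
    genome so the full pipeline is verifiable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    Biostrings,
    S4Vectors,
    methods,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    rtracklayer
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
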
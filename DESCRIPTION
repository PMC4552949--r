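Package: lsgscan
Title: Lineage-Specific Gene Identification and Origin Analysis for Nematode Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for genome-wide identification and
    characterization of lineage-specific genes (LSGs) in Caenorhabditis
    elegans. Classifies proteins into species-specific (SSG), genus-specific
    (GSG) and evolutionarily conserved (EC) genes by hierarchical homology
    screening against clade-stratified proteome panels with length-dependent
    scoring matrices and Karlin-Altschul E-values; characterizes gene
    structure (length, exon number, protein size, GC content) with one-way
    ANOVA across groups; infers mechanisms of origin by complete-overlap
    tests against transposable-element and paralog annotation tracks with
    inclusion-exclusion accounting; screens for retrogenes and chimeric genes
    via six-frame translated matching, adjacent-match merging, parental
    assignment and intron-aware spliced alignment; and profiles expression
    across developmental stages from transcript mappings and read placements
    with RPKM normalization. A synthetic-world generator plants genes of
    known class, origin and expression so that every classifier can be
    validated against ground truth without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    methods,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
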
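Package: kiwipan
Title: Pan-Gene and Structural-Variant Analysis for Haplotype-Resolved
    Kiwifruit Genomes
Version: 0.1.0
Authors@R:
    person("kiwipan", "developers", email = "kiwipan@example.org",
           role = c("aut", "cre"))
Description: Builds a protein-coding pan-genome and a non-redundant
    structural-variant (SV) catalog from haplotype-resolved genome
    assemblies. Classifies orthogroup clusters into core, softcore, shell
    and cloud compartments, computes pan/core saturation curves, merges
    per-haplotype SV calls into a non-redundant catalog with carrier sets,
    classifies each SV's genomic context (exonic, intronic, promoter,
    downstream, intergenic), scans for SV hotspots with a sliding window,
    detects flesh-colour-group-specific SVs, intersects promoter SVs with
    differential expression, computes NG86 Ka/Ks for haplotype gene pairs,
    and constructs a coordinate-preserving variation graph (GFA 1.0) with
    haplotype paths. Ships a fully specified synthetic 14-haplotype cohort
    generator with planted truth so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
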
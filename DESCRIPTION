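Package: mirvar
Title: Prioritisation of Small Genetic Variants in Dairy microRNA Genes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Extracts, classifies and summarises small genetic variants
    (SNPs and InDels shorter than 60 bp) lying in or near microRNA genes
    expressed in the ruminant mammary gland or present in milk, and falling
    inside dairy or mastitis QTL intervals. Implements seed-aware variant
    localisation (seed, mature arm, precursor, flanking windows), allele
    frequency computation from multi-breed genotype panels, a configurable
    filtering cascade with per-stage logging, flank-anchored coordinate
    transposition between assemblies, seed-complementarity target-site
    prediction with gained/lost target diffing, and a deterministic
    synthetic-data generator with planted ground truth for end-to-end
    verification.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite
biocViews: GeneticVariability, SNP, GenomicVariation, Annotation,
    Sequencing, VariantAnnotation
Config/testthat/edition: 3
RoxygenNote: 7.3.3
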
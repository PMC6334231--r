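Package: phyloBaits
Title: Targeted-Enrichment Bait Design and Post-Capture Locus Quality
    Control for Phylogenomics
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A toolkit for designing hybridization bait kits from
    multi-species transcriptome assemblies and for quality control of
    the loci recovered by target capture. The design arm extracts and
    translates open reading frames, reduces redundancy by greedy
    identity clustering, screens out multi-copy gene families,
    identifies orthologs by reciprocal-best-hit search against focal
    taxa, and applies phylogeny-aware identity, length and congruence
    filters before tiling degenerate 120-bp baits across the surviving
    exonic targets. The quality-control arm implements 75/75 locus
    selection from recovery-length tables, shared-locus set logic
    between clades, gene-tree paralog screening by monophyly testing,
    parsimony-informative-site statistics, low-support branch
    collapsing, supermatrix concatenation with per-locus partitions,
    and per-branch gene-tree concordance. A synthetic-data generator
    simulates multi-species transcript sets (orthologs, paralog
    families, splice isoforms, UTR-flanked CDS, clade rate
    heterogeneity) and stochastic capture recovery so every stage can
    be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    S4Vectors,
    SummarizedExperiment,
    ape,
    phangorn
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Phylogenetics, Alignment, SequenceMatching, Software
RoxygenNote: 7.3.3
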
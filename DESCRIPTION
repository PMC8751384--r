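Package: strainpop
Title: Strain-Level Population Genomics and Co-Occurrence Analysis for
    Metagenome-Derived Bacterial Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for strain-resolved evolutionary analysis of bacterial
    populations sampled by shotgun metagenomics, motivated by comammox
    Nitrospira communities in groundwater-fed rapid sand filters. Implements
    read-filter and coverage gating, SNP calling from per-site allele
    counts, nucleotide diversity (pi), linkage disequilibrium (D'),
    pN/pS with Nei-Gojobori potential-site counting, Hudson F_ST with
    high-F_ST locus and selective-sweep scans, positive-selection outlier
    detection, and a compositional co-occurrence layer (count-zero
    multiplicative replacement, centered log-ratio transform,
    proportionality rho with permutation FDR, Jaccard dissimilarity and
    Mantel tests). A synthetic haplotype-community simulator with full
    ground truth supports calibration and testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    Rsamtools,
    data.table,
    vegan,
    yaml,
    stats,
    utils,
    methods,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
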
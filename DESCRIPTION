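Package: paracnv
Title: Detection of Gene Copy Number Variants Under Parallel Selection
    from Read Depth
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies gene copy number variants (GCNVs) shared between
    two groups of low-coverage resequenced individuals, the read-depth
    signature of parallel selection. Counts deduplicated single-end reads
    over gene bodies, filters weakly covered genes, normalizes by
    genome-wide mapped totals, and screens genes with a negative-binomial
    exact test under a common dispersion with Benjamini-Hochberg FDR
    control. Calls are made robust to mapping parameters by intersecting
    significant sets across mapping-stringency replicates, assessed
    against a label-permutation null for the number of detected GCNVs,
    and distinguished as duplications by counting read-backed allelic
    haplotypes at nearby SNV pairs (three or more alleles cannot come
    from one diploid locus). A simulator generates count matrices and
    collapsed-paralog reads with known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    graphics,
    Rcpp,
    GenomicRanges,
    IRanges,
    Rsamtools,
    vcfR,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    edgeR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
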
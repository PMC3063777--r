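Package: strainseq
Title: Cross-Strain RNA-Seq Differential Expression with Allele-Bias
    Assessment and Microarray Concordance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A desk-scale pipeline for comparing gene expression between two
    inbred mouse strains (C57BL/6J and DBA/2J) by digital mRNA counting.
    Builds per-gene union-exon models from transcript annotations with
    inter-gene overlap removal, aligns trimmed short reads with a
    deterministic seeded mismatch-counting aligner, counts read start
    positions into union exons, normalizes libraries by the upper quartile
    of nonzero counts, estimates a common negative-binomial dispersion by
    conditional maximum likelihood on quantile-adjusted pseudocounts, and
    tests differential expression with the negative-binomial exact test
    (with a Poisson likelihood-ratio comparator and Storey q-values).
    Assesses allele-specific mapping bias by realigning the non-reference
    strain's reads to a SNP-substituted genome and classifying per-gene
    changes in differential-expression status, and evaluates concordance of
    detection and fold-change direction against probe-level results from
    two microarray platforms.  A seeded synthetic-data generator produces
    genomes, annotations, SNPs, strain-specific reads, negative-binomial
    count matrices and probe tables with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    edgeR
Config/testthat/edition: 3
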
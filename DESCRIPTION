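Package: vitiSDR
Title: Haplotyping and Flower-Sex Prediction for the Grapevine Sex-Determining Region
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to model and analyse the grapevine sex-determining region
    (SDR). Provides an explicit model of the f/M/H1/H2 SDR haplotypes, the
    three recombination breakpoints and the A-D region structure; simulators
    for diploid genotype panels, per-site allele read depths, bulked-pool
    window depth tracks and allele-specific expression counts; scans for
    sex-linked SNPs (cosegregation, minor allele frequency, exact
    Hardy-Weinberg test, linkage disequilibrium); bulk-segregant read-depth
    delineation of the SDR; chromosome painting, recombination-breakpoint
    detection and classification of accessions into the ten diploid
    haplotype combinations; Bayes-factor region genotyping and flower-sex
    phenotype prediction from DNA or RNA allele depths, including the
    VviINP1 8 bp indel marker; and a permutation test for association
    between allele-specific expression and flower-sex factors.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
biocViews: Genetics, SNP, Sequencing, Software
RoxygenNote: 7.3.3
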
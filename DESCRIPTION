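Package: msreprof
Title: MSRE-Seq CpG Methylation Profiling and Group Discrimination
Version: 0.1.0
Authors@R: person("Genome", "Profiling", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies per-CpG methylation state from methyl-sensitive
    restriction enzyme sequencing (MSRE-seq) libraries. HpaII (CCGG) cut-site
    evidence in aligned short reads is decomposed into digest-end counts,
    motif-spanning counts and local coverage to reconstruct paired M
    (fully-methylated) and U (fully-unmethylated) metrics per site. Downstream
    analyses discriminate two sample groups: a negative-binomial exact test
    with Benjamini-Hochberg FDR control, signed differential methylation load
    over genes and genomic domains, non-metric multidimensional scaling with
    confidence ellipses and a permutation separation test, and hierarchical
    clustering of top-discriminating sites with bootstrap branch support. A
    seeded read simulator (HpaII digestion, random shearing, 71 bp single-end
    reads, bimodal methylation priors) provides ground truth for every stage.
License: MIT
Encoding: UTF-8
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    Rsamtools,
    S4Vectors,
    ape,
    jsonlite,
    methods,
    stats,
    utils,
    vegan
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
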
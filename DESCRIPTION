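Package: cfmeth
Title: Differential Methylation and CpG-Island Hotspot Analysis of Pooled
    Cell-Free DNA Methylomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of pooled plasma cell-free DNA (cfDNA) whole-genome
    bisulfite methylomes: readers for Bismark cytosine-report and coverage
    dialects, per-base two-group differential methylation (Fisher exact test,
    differential methylation values, Benjamini-Hochberg q-values), genomic
    context annotation, CpG-island hypermethylation hotspot calling, pool
    similarity analyses (Pearson correlation, Ward clustering, PCA, percent
    methylation histograms), cross-platform concordance statistics, and a
    beta-binomial simulator of pooled bisulfite methylomes with planted
    ground truth for end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
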
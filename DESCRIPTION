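Package: panelCNV
Title: Exon-Level Copy Number Variant Detection in Targeted Gene Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Read-depth based detection of exon-level germline copy number
    variants in targeted gene-panel sequencing (hybridization or amplicon
    capture). For every capture probe the package fits a set of bootstrapped
    linear regressions of probe depth against the per-sample (per-pool)
    median depth, derives an empirical read-depth ratio distribution with a
    95 percent confidence interval per probe and sample, segments per-gene
    ratio profiles with circular binary segmentation, rescues short runs of
    strong probe-level signals, and assigns each candidate a 0-5 confidence
    score from five quality criteria. Includes sample quality control by
    inter-sample depth correlation, chromosome X normalization by gender, a
    synthetic-cohort generator with implanted CNVs for validation, plotting
    of per-sample and per-gene ratio profiles, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomeInfoDb,
    GenomicRanges,
    SummarizedExperiment,
    GenomicAlignments,
    Rsamtools,
    ggplot2,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
biocViews: CopyNumberVariation, Sequencing, TargetedResequencing, Coverage
RoxygenNote: 7.3.3
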
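Package: metCNA
Title: Intermetastatic Copy-Number Heterogeneity Analysis for Multi-Lesion Tumor Cohorts
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis of segmented total copy-number profiles from
    multiple metastatic lesions per patient. Harmonizes sample-wise segments
    into the smallest genomic regions of overlap, calls gains and losses
    relative to each lesion's median genome-wide copy number, computes
    genome-wide aberration burden, quantifies intrapatient intermetastatic
    heterogeneity by distance-, correlation- and discordant-gene-based
    estimators, detects and classifies high-level amplifications relative to
    ploidy, aggregates driver-gene mutation calls into co-mutation strata,
    and applies cancer-specific survival conventions (Kaplan-Meier, log-rank,
    log-rank trend, Cox regression). Includes a synthetic cohort generator
    emulating colorectal-cancer-typical aberration landscapes for validation
    and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    survival
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: CopyNumberVariation, Survival, Software
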
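Package: dartpool
Title: Diversity and Population Structure Analysis of Pooled DArTseq SNP Panels
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing codominant DArTseq SNP reports from pooled
    cultivar samples, as used in gene-bank surveys of self-pollinating crops.
    Reads the two-row DArTseq dialect, applies reproducibility, call-rate and
    minor-allele-frequency filters, and computes per-locus and per-group
    diversity statistics (PIC, observed and unbiased expected heterozygosity,
    fixation index, rarefied allelic richness), transition/transversion
    accounting, sliding-window genome scans with Wright's FST and its
    contrast-enhancing power transform, unique-allele turnover between
    breeding periods, Jaccard distances with principal coordinate analysis,
    distance-based AMOVA with a permutation test, method-of-moments
    identity-by-descent duplicate detection, maximum-likelihood admixture
    inference with Evanno delta-K model choice, and M-strategy core-collection
    extraction. A seeded synthetic-panel generator with a recorded truth
    object supports end-to-end testing of every stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    ape,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
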
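Package: mqtlewas
Title: mQTL-Aware Epigenome-Wide Association Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for incorporating methylation quantitative trait loci
    (mQTLs) into epigenome-wide association studies (EWAS). Implements
    per-CpG cis-mQTL discovery with a permutation test and a
    beta-approximated adjusted P value, inverse-variance fixed-effects
    meta-analysis of per-dataset mQTL results into a per-CpG mQTL
    database, paired EWAS linear models with and without the matched
    mQTL covariate (partial F-tests and effect-size-change statistics),
    LD-based cross-dataset mQTL concordance, genomic-feature enrichment
    of mQTL-matched CpGs, reference-based cell-type deconvolution, and a
    synthetic multi-stratum cohort generator with planted effects for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    GenomeInfoDb,
    vcfR,
    pracma,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    metafor,
    fitdistrplus
Config/testthat/edition: 3
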
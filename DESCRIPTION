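Package: niptcnv
Title: Maternal Copy-Number Variant Calling from Low-Coverage NIPT cfDNA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detection and cohort-level analysis of maternal copy-number
    variants (CNVs) from low-coverage cell-free DNA sequencing of the kind
    produced by genome-wide non-invasive prenatal testing (NIPT). Read
    counts on a fixed 20 kb bin grid are normalized in two steps (LOESS GC
    correction followed by reference-panel PCA denoising on autosomes),
    segmented with a permutation-based circular binary segmentation
    algorithm, and thresholded into maternal calls (segments of at least
    200 kb whose signal deviation exceeds 75% of the heterozygous
    single-copy shift). Cohort utilities cluster recurrent calls into
    multiple occurring variants (MOVs), estimate population frequencies,
    contrast them with external database frequencies by chi-squared tests,
    and flag chromosomes with outlying variants-per-megabase density. A
    synthetic-cohort generator produces binned cfDNA-like profiles with a
    known truth set (GC bias, low-rank batch artifacts, negative-binomial
    noise, fetal-fraction background) so the whole pipeline is testable
    without patient data.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
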
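Package: devilscan
Title: Temporal Selection Scans for Replicated Wild Populations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects genomic regions under parallel selection from temporally
    sampled SNP data in replicate populations, motivated by the rapid
    evolutionary response of Tasmanian devils to devil facial tumour disease.
    Implements RAD-seq style SNP filtering, an allele-frequency-change scan
    with LD pruning and cross-population candidate-region intersection,
    site-level extended haplotype homozygosity (EHHS), integrated EHH and the
    temporal Rsb contrast on phased haplotypes, a Fisher's-method composite
    window statistic, region randomization tests of functional annotation,
    temporal effective-population-size estimation (Jorde-Ryman two-sample
    method), per-SNP Wright-Fisher maximum-likelihood selection-coefficient
    estimation, and a forward Wright-Fisher simulator with linked selection
    for calibration and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    vcfR,
    GenomicRanges,
    IRanges,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
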
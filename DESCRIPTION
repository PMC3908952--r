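Package: mosaicall
Title: Bayesian SNP Calling with Allele Frequency Spectrum Priors for
    Low-Level Mosaic Variant Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Single- and multi-sample Bayesian SNP calling from read
    pileups, with configurable allele-frequency-spectrum (AFS) priors
    (Wright-Fisher 'full', 'cond2' and 'flat') and an optional EM
    refinement of the spectrum.  Includes a correlated sequencing-error
    model for genotype likelihoods, a deterministic mosaic-read simulator
    that emits valid SAM text for a single variant site over depth by
    mutant-fraction grids, minimum-detectable allele-fraction sensitivity
    sweeps with Wilcoxon signed-rank comparisons between caller
    configurations, and two-tier hard filters built on PV4 bias
    statistics, Hardy-Weinberg tests, homopolymer/repeat exclusion and
    cross-sample gene recurrence.  Designed for detecting postzygotic
    (somatic mosaic) point mutations present in only a fraction of reads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), withr, vcfR, optparse
Config/testthat/edition: 3
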
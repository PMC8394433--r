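Package: memsi
Title: Microsatellite Instability Calling from Unaligned Reads by Mixture
    Expectation-Maximisation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects microsatellite instability (MSI) from small-panel
    amplicon sequencing of the five Bethesda mononucleotide microsatellites
    (BAT-25, BAT-26, NR-21, NR-24, NR-27). Read-length distributions of each
    microsatellite are recovered directly from unaligned, quality-unfiltered
    paired-end FASTQ reads by Smith-Waterman anchoring of the locus flanking
    sequences; each observed distribution is then modelled as a mixture of up
    to three location-shifted copies of an empirical reference profile built
    from microsatellite-stable control samples, fitted by
    Expectation-Maximisation. A likelihood-ratio test with a Monte Carlo
    power gate converts the fit into per-locus stable / unstable /
    non-contributory calls and a sample-level MSI / MSS verdict. Includes an
    amplicon read simulator with a replication-slippage (PCR stutter) noise
    model, and concordance statistics (Cohen's kappa, sensitivity,
    specificity, predictive values) for method comparison studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    Biostrings,
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
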
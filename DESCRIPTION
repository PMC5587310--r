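Package: xtriad
Title: X-Linked Association Analysis for Case-Parent Triads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Chromosome-wide association analysis of X-linked markers in
    case-parent triads. Fits a haplotype-based log-linear penetrance model
    with a multiplicative dose-response in girls and two alternative
    couplings for hemizygous boys (with and without X-inactivation), using
    an EM algorithm for haplotype frequencies under missing genotypes and
    quasi-Newton maximisation of the observed-data likelihood for relative
    risks. Provides sliding-window scans across a marker map with
    likelihood-ratio p-values and Benjamini-Hochberg q-values, PLINK-style
    ped/map input with quality-control filters, an exact simulator of
    case-ascertained triads, and Monte-Carlo power estimation across grids
    of relative risks, allele frequencies and sample sizes.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
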
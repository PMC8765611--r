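Package: ehhscan
Title: Extended Haplotype Homozygosity Selection Scans for Phased and
    Unphased Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects recent positive selection from haplotype data using the
    extended haplotype homozygosity (EHH) family of statistics: iHS within a
    population and XP-EHH and Rsb between populations. Implements both the
    classical phased estimators and homozygote-based estimators for unphased
    diploid genotypes, together with major/minor-allele scoring for
    unpolarized variants, sliding-window delineation of candidate regions,
    a desk-scale neutral and selective-sweep simulator, and false discovery
    rate / power evaluation of whole-genome scans against simulation truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
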
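Package: haplomember
Title: Haplotype-Based Membership Inference from Genomic Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Infers whether a rare haplotype is present in a private genome
    database from its published summary statistics alone -- either a per-site
    minor-allele frequency table or a Beacon-style presence/absence table --
    without access to any target individual's genome.  Implements known-
    haplotype inference from frequency tables (KHF) by exact enumeration of
    integer haplotype-count solutions to the per-site linear constraints,
    known-haplotype inference from Beacon tables (KHB) by logical constraint
    propagation plus Monte-Carlo approximation of multinomial cumulative
    probabilities, and reconstruction of novel haplotypes unseen in the public
    reference (NHF) by exact minimisation of the total minor-allele count.
    Includes a likelihood-ratio test with an empirical null distribution,
    power and false-positive-rate harnesses, SNV-based baseline attacks for
    comparison, and a synthetic-data generator emulating haploblock structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
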
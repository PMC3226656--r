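Package: cdhtest
Title: Collapsed Double Heterozygosity Tests for Low-Frequency
    Loss-of-Function Alleles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects multiple low-frequency loss-of-function alleles acting
    recessively and as compound heterozygotes at one locus using the collapsed
    double heterozygosity (CDH) test: a 1-df contingency test on case/control
    counts after collapsing the homozygote and compound-heterozygote cells of
    the 3x3 cross-genotype table of two SNPs.  Includes the closed-form
    expected-count power theory for the recessive plus compound-heterozygote
    model, Monte Carlo power and type-I simulation harnesses, a weighted sum
    statistic (WSS) comparator, two-locus haplotype EM with LD statistics and
    a diplotype-based CH-vs-DH follow-up test, and a sliding-window genome
    scanner with Bonferroni bookkeeping.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
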
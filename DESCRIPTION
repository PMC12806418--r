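Package: epistasim
Title: Simulation of Case-Control SNP Data with High-Order Epistasis Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Constructs penetrance tables for epistasis models of arbitrary
    order with marginal effects, solving the relative penetrance against a
    target disease prevalence or heritability under Hardy-Weinberg genotype
    frequencies, and generates case-control SNP genotype datasets by fragment
    resampling from a real or synthetic sampling pool so that realistic minor
    allele frequencies (and local linkage disequilibrium) are preserved.
    Includes a synthetic pool generator with known allele frequencies and
    optional block LD for fully self-contained benchmarking of epistasis
    detection methods.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
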
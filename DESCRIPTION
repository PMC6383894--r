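Package: hwexeq
Title: Equivalence Testing for Hardy-Weinberg Equilibrium at X-Chromosomal Markers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tests for goodness (rather than lack) of fit of diallelic
    X-chromosomal markers to the Hardy-Weinberg model. Disequilibrium is
    measured jointly for the two sexes by combining the log relative excess
    heterozygosity among females with the log odds ratio between the female
    and male allele frequencies into a Euclidean distance, and approximate
    compatibility with the model is established when an upper confidence
    bound for this distance falls below an equivalence margin. The package
    provides the per-SNP decision procedure with a sparse-count correction,
    exact finite-sample rejection probabilities by full enumeration of the
    trinomial-by-binomial outcome space, the extended chi distribution
    needed for power against alternatives in perfect equilibrium, closed
    sample-size formulas for study planning, a combined chi-squared
    lack-of-fit comparator with a Monte Carlo harness, and a command-line
    interface over tab-separated count tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
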
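Package: aachron
Title: Positional Amino-Acid Gradients and the Chronology of the Genetic
    Code
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies 5'-to-3' positional gradients of amino-acid species
    in protein sequences and relates them to hypothesised orders of
    amino-acid inclusion in the genetic code. Computes size-standardised
    mean residue positions per protein, per-group aggregation with exact
    binomial sign tests, Fisher combined probabilities and a
    false-discovery-rate adjusted critical value for dependent tests,
    correlations of per-protein gradients with external covariates, and
    analyses of pairwise residue contact-energy matrices against
    inclusion-rank differences. Ships a synthetic-sequence generator with a
    tunable positional gradient and substitution noise so that every
    pipeline stage can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Config/testthat/edition: 3
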
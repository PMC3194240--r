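Package: epibnb
Title: Epistasis Detection in Case-Control SNP Data via Bayesian-Network
    Parent-Set Search
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Detects epistatic (gene-gene) interactions in case-control
    genotype data by learning the parent set of a binary disease-status
    node in a Bayesian network.  Local scores (maximum log-likelihood,
    AIC, BIC with a rescaled small-sample penalty, and BDe) are maximised
    over subsets of candidate SNPs by a depth-first branch-and-bound
    search with a configurable look-ahead pruning rule.  Includes a
    likelihood-ratio (G2) marginal screen for candidate selection, a
    two- and three-locus penetrance-model simulator for case-control
    data with controlled minor-allele frequency and linkage
    disequilibrium, readers and writers for delimited and PLINK PED/MAP
    genotype text formats, and a power-evaluation harness for
    simulation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), optparse, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
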
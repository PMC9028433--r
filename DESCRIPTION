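Package: drugcombinet
Title: Network-Pharmacology Prioritization of Minimal Drug Combinations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An integrated network-pharmacology pipeline that prioritizes
    minimal drug combinations for a disease from paired case/control
    expression data, prior-knowledge association layers and a drug library
    (targets, SMILES strings, perturbational replicate profiles).  Candidate
    genes are scored by paired Wilcoxon and variance F tests combined with
    log fold change into a significance score; a consensus gene
    co-expression network is inferred with an ensemble of CLR, ARACNE and
    MRNET over correlation and mutual-information estimators; the network is
    filtered by a three-category (interaction, regulation, functional)
    multilayer prior; hub genes are ranked by Borda aggregation of
    centralities; per-drug features (Hamming-Ipsen-Mikhailov distances
    between mechanism-of-action networks, Levenshtein distances between
    SMILES, target shortest-path dispersion, network effect scores) feed a
    five-objective NSGA-II genetic algorithm with a Hall of Fame that
    searches for small sets of mutually dissimilar, well-spread,
    high-coverage drugs.  Includes a synthetic-fixture generator with
    planted ground truth for end-to-end validation and a command-line
    interface for each pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
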
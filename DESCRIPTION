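Package: divergeScan
Title: Selection Scans on Candidate Genes Under a Fitted Two-Population
    Divergence Model
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for detecting selection on candidate genes while accounting
    for population divergence. Fits a two-population divergence demographic
    model to control loci (sequences and microsatellites) by approximate
    Bayesian computation with local linear regression, simulates
    coalescent-based null distributions for per-gene neutrality statistics
    (Tajima's D, normalized Fay and Wu's H, Hudson's FST) with outgroup
    misorientation modelling, performs pairwise and maximum-likelihood HKA
    tests, computes pairwise Nei-Gojobori dN/dS between orthologs, and
    relates test outcomes to the position of each gene in a metabolic
    pathway. Includes a synthetic-data generator emulating a resequencing
    study of a structured crop sample with an outgroup, so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    seqinr
Config/testthat/edition: 3
biocViews: PopulationGenetics, Coalescent, Software, StatisticalMethod
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'io.R'
    'sumstats.R'
    'divsim.R'
    'abc.R'
    'dnds.R'
    'hka.R'
    'neutrality.R'
    'pathway.R'
    'pipeline.R'
    'synthetic.R'
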
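Package: coaldrop
Title: Coalescent and Gene Drop Simulation of Sequence, SNP and Phenotype Data
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates whole-genome sequence haplotypes under a Markovian
    coalescent with recombination and a piecewise-linear effective
    population size history, drops them through a mammalian-style pedigree
    by Mendelian inheritance with recombination, samples SNP chips and
    candidate quantitative trait loci, and generates additive breeding
    values and phenotypes at a target heritability.  Produces benchmark
    data sets for genomic selection and genome-wide association studies,
    including training/validation splits by pedigree generation, with
    bit-packed gamete storage so that sequence-level gene dropping through
    large pedigrees stays cheap.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    data.table,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
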
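Package: steppekin
Title: Geographical Exogamy, Inbreeding and Runs of Homozygosity in
    Structured Human Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for the joint analysis of marital dispersal and genetic
    inbreeding in SNP-array cohorts with accompanying ethno-demographic
    surveys. Quantifies geographical exogamy from spousal birthplace
    distances (kernel-density antimode threshold, per-population exogamy
    rates, distance classes), estimates per-individual inbreeding
    coefficients with a two-state identity-by-descent hidden Markov model
    fitted over random sparse marker subsets (F-Median/A-Median, boundary
    likelihood-ratio test, five-way parental mating-type classification
    against simulated reference clouds), calls and classifies runs of
    homozygosity (fixed thresholds and per-population three-component
    Gaussian mixtures on log lengths), computes allele-sharing
    dissimilarity, relative exclusion, haplotypic heterozygosity over
    low-recombination blocks and excess homozygosity, and assembles
    distance-binned exogamy-versus-inbreeding comparison reports. Includes
    a pedigree gene-dropping simulator with known autozygosity ground
    truth so every stage is testable without restricted genotype data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    geosphere,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
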
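Package: maizediv
Title: Genetic Diversity, Kinship and Population Structure of Maize Germplasm Panels
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for assessing genetic diversity and vulnerability of
    commercial crop germplasm from diploid biallelic SNP panels: quality
    control (call rate and minor allele frequency filters), per-locus and
    per-group diversity statistics (gene diversity, PIC, heterozygosity,
    MAF), private-allele detection, allele-frequency correlations between
    breeding groups, Nei DA genetic distances with UPGMA clustering and
    locus-bootstrap node support, a VanRaden-style genomic relationship
    matrix with Fst and effective population size estimation, and a
    Bayesian admixture (STRUCTURE-style) Gibbs sampler with Evanno delta-K
    model selection. Includes a Balding-Nichols synthetic genotype
    generator for inbred panels, F1 single-cross hybrids and admixed
    populations, and an end-to-end pipeline driver.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, ape, jsonlite, Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr, phangorn, yaml, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
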
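Package: ploidypop
Title: Mixed-Ploidy SNP Analysis for Interfertile Shrub Birch Species
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A multicriteria workflow for separating interfertile mixed-ploidy
    shrub birch (Betula) species from targeted SNP data. Infers per-individual
    ploidy from the density profile of allelic ratios at heterozygous sites,
    assembles clone-filtered diploid and diploid-tetraploid genotype datasets,
    infers genetic clusters by discriminant analysis of principal components
    (DAPC) and by a binomial EM admixture model with Evanno delta-K model
    selection, computes observed/expected heterozygosity, FIS and pairwise
    Weir-Cockerham FST, collapses chloroplast SNPs to uniquely informative
    haplotypes and reports their sharing across nuclear clusters, and matches
    leaf morphology against published species criteria. Includes a synthetic
    mixed-ploidy dataset generator (Balding-Nichols cluster frequencies,
    beta-binomial allele-specific read counts, clones, hybrids, chloroplast
    capture) so every stage is testable against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
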
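Package: zygoticLD
Title: Zygotic Linkage Disequilibrium and Its Genic Components from Unphased SNP Genotypes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Estimation and testing of the full hierarchy of two-locus genic
    disequilibria that is identifiable from unphased biallelic SNP genotypes
    in diploid populations that need not be in Hardy-Weinberg equilibrium:
    single-locus Hardy-Weinberg disequilibrium and fixation indices, gametic
    LD (via the two-locus EM algorithm), composite digenic LD, trigenic and
    composite quadrigenic disequilibria, and zygotic LD (the double-homozygote
    association). Each component is tested with a one-degree-of-freedom
    chi-square statistic built either from n times a squared correlation or
    from a multinomial delta-method sampling variance, and summarized with the
    generalized squared correlation phi-square. Genome-scan utilities
    enumerate syntenic and non-syntenic marker pairs and aggregate strength
    and test power over physical-distance bins, minor-allele-frequency
    classes and chromosomes. Includes simulators for random-union-of-gametes
    populations, saturated two-locus genotype distributions, and admixed
    (multi-breed composite) populations with known population-level
    disequilibria, so every estimator can be validated against exact truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils
Suggests: testthat (>= 3.0.0), vcfR, jsonlite, optparse, knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
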
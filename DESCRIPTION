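Package: lcgblup
Title: Genomic Prediction from Low-Coverage Sequencing via Founder-Haplotype
    Imputation and GBLUP
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis pipeline for genomic selection based on
    low-coverage whole genome sequencing. Simulates structured diploid
    populations descended from a small founder-haplotype panel together with
    correlated quantitative traits and shallow sequencing read counts; imputes
    posterior genotype probabilities and expected allele dosages without a
    reference panel using a founder-haplotype hidden Markov model fitted by
    EM; scores imputation by genotypic concordance and dosage r-squared with
    minor-allele-frequency stratification; builds genotype-, dosage- and
    pedigree-based relationship matrices with site filtering and LD pruning;
    fits single- and two-trait GBLUP mixed models by average-information REML;
    and evaluates prediction accuracy and dispersion bias by k-fold
    cross-validation on fixed-effect-corrected phenotypes.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
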
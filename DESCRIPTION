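Package: pdoscreen
Title: Genomic Concordance and Drug-Screen Analytics for Patient-Derived
    Organoids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for matched tumor/organoid cohorts in bladder
    cancer: allele-specific copy-number indices (allele-specific ploidy and
    genomic burden), gene-wise copy-number similarity scoring between matched
    and random sample pairs, somatic SNV quality filtering, tumor mutational
    burden, shared/private concordance and cancer-cell-fraction clonality,
    gene-set over-representation with cross-sample recurrence shortlisting,
    drug-screen plate normalization with vehicle-referenced z-scores and
    ANOVA/Dunnett hit calling, and linear-mixed-model pharmacogenomic
    association with false-discovery-rate control. Includes a synthetic
    matched-cohort generator with planted genotype-drug effects so every
    stage is testable without access to controlled patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    lmerTest,
    multcomp,
    fgsea,
    rtracklayer,
    ape
Suggests:
    vcfR,
    jsonlite,
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
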
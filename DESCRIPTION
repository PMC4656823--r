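Package: loctransfer
Title: Transferability and Trans-Ethnic Fine-Mapping of GWAS Risk Loci
Version: 0.1.0
Authors@R:
    person("loctransfer", "developers", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to evaluate whether GWAS susceptibility loci discovered in
    one population replicate in another, and to fine-map them using the
    shorter haplotype blocks of the replication sample. Implements a
    case-control quality-control cascade (call rate, duplicates, sex
    discordance, IBD relatedness, variant missingness/HWE/MAF and
    imputation-quality filters), logistic regression on imputed allelic
    dosages with covariate and principal-component adjustment, genomic
    control, two-locus EM haplotype frequency estimation, D-prime
    confidence-interval haplotype blocks (Gabriel method), a spectral
    effective-number-of-tests correction, exact/local transferability
    classification, block-size fine-mapping comparison, and analytic plus
    simulation-based replication power. A synthetic-cohort generator with
    block-structured LD, dosage imputation noise and injected QC flaws makes
    the whole pipeline testable without external genotype data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    optparse,
    jsonlite,
    VariantAnnotation,
    SummarizedExperiment,
    S4Vectors,
    GenomeInfoDb,
    BiocGenerics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
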
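# loctransfer

Transferability and trans-ethnic fine-mapping of GWAS risk loci in a
case-control replication cohort.

## The scientific problem

GWAS discoveries are dominated by European- and Asian-ancestry cohorts.
Whether a reported susceptibility locus matters in another population —
and where exactly its signal localises — must be established separately.
`loctransfer` implements the standard evaluation for a replication
cohort genotyped (or imputed) at the reported loci:

1. **Exact transferability.** The reported index SNP replicates when its
   association p-value is below 0.05 *and* the effect direction for the
   harmonized risk allele matches the original report.
2. **Local transferability.** Otherwise, every SNP in the haplotype
   block containing the index SNP (blocks by the D′ confidence-interval
   method of Gabriel et al.) is tested, with p-values adjusted by the
   effective number of independent tests
   `N_eff = (Σλ_k)² / Σλ_k²`, where λ_k are the eigenvalues of the
   block's SNP correlation matrix; the locus replicates locally when the
   best in-LD SNP has `p·N_eff < 0.05`.
3. **Fine-mapping.** Because LD decays faster in African-ancestry
   genomes, a locus transferable to such a cohort usually maps to a
   *shorter* haplotype block than in the discovery population, often
   with a neighbouring SNP beating the index SNP's p-value. The package
   compares block spans between the study sample and a discovery-ancestry
   reference panel.

Supporting machinery: a full sample/variant QC cascade (call rate,
duplicate and relatedness pruning by method-of-moments IBD PiHat, sex
discordance, missingness, exact Hardy–Weinberg test, MAF, imputation
quality), logistic regression on imputed allelic dosages with age, sex,
BMI and genotype-PC covariates, genomic-control λ, exact binomial
sign-consistency testing, and analytic + simulated replication power for
a per-allele OR at one-sided α. A synthetic-cohort generator with
block-structured LD, dosage noise at a target imputation r², and planted
QC flaws makes every stage testable without external data.

## Worked example

```r
library(loctransfer)

# a panel with 3 LD blocks of 10 SNPs, |D'| = 1 within blocks
panel <- simulate_panel(3, 10, 200, within_block_ld = 1,
                        maf_range = c(0.2, 0.5), seed = 42)
g <- simulate_genotypes(panel, 150, seed = 7)

# Gabriel blocks recover the planted partition
pl <- pair_ld_table(g)
gabriel_blocks(pl, g$variants$pos, variant_ids_ = g$variants$id)[, 1:6]
#>    chrom start_bp  end_bp first last n_snps
#> i      1  1000000 1009000     1   10     10
#> i1     1  1059000 1068000    11   20     10
#> i2     1  1118000 1127000    21   30     10

# effective number of tests inside one block of 10 correlated SNPs
effective_tests(g[, 1:10])
#> <neff_result> K = 10, n_eff = 1.3185

# exact HWE test and the dosage logistic fit against closed forms
hwe_exact_test(1, 0, 1)               # 0.3333333
d <- c(rep(1, 40), rep(0, 60), rep(1, 20), rep(0, 80))
y <- c(rep(1, 100), rep(0, 100))
logistic_dosage_fit(d, NULL, y)[, c("beta", "se")]
#>      beta     se
#> 0.9807971 0.3227486

# replication power for OR 1.2 at control RAF 0.2 (1035 cases / 740 controls)
power_analytic(power_spec(1.2, 0.2, 1035, 740, 0.05))
#> 0.7064398

# directional consistency of 76 of 103 evaluated loci
sign_consistency_test(76, 103)
#> 1.090969e-06
```

The numbers above are printed by the code as shown: three planted blocks
recovered exactly; `n_eff` far below K = 10 reflects the within-block
correlation; the 2×2 logistic fit equals the closed-form log odds ratio
`ln(40·80/(60·20)) = 0.9808` with SE `√(1/40+1/60+1/20+1/80) = 0.3227`;
76/103 consistent directions is ~10⁻⁶ under a fair coin, i.e. strong
excess directional agreement.

The full pipeline (QC → PCA → dosage association → blocks + N_eff →
transfer calls → fine-mapping → sign-consistency summary) is driven by
`run_pipeline()`, or from the shell:

```sh
exec/loctransfer simulate --out-prefix cohort --seed 1
exec/loctransfer run --vcf cohort.vcf --samples cohort.samples.tsv \
    --catalog inst/extdata/example_index_catalog.tsv --out results/
exec/loctransfer power --or-values 1.1,1.2,1.3 --raf-values 0.1,0.2 --out power.tsv
```

## Documentation

`vignettes/methods.Rmd` describes the models, the QC cascade, the LD and
multiple-testing machinery, the synthetic-data generator and its
limitations, and every numerical/design choice with its rationale.
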
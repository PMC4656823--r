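---
title: "Methods: locus transferability, LD blocks and trans-ethnic fine-mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: locus transferability, LD blocks and trans-ethnic fine-mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

A susceptibility locus discovered by GWAS in one population is
*transferable* to a second population when it shows association there too.
`loctransfer` implements the standard two-route evaluation for a
case-control replication cohort:

* **Exact transferability**: the originally reported index SNP itself is
  associated at p < 0.05 with the same direction of effect for the same
  (harmonized) allele.
* **Local transferability**: when the index SNP is not associated, every
  SNP of the haplotype block containing it is tested, with p-values
  adjusted for the effective number of independent tests in the block.

Because African-ancestry genomes carry systematically shorter haplotype
blocks than European or East-Asian genomes, a replication cohort of
African ancestry can also *fine-map* a transferable locus: the block
around the lead SNP is shorter than in the discovery population, and a
neighbouring SNP often carries a stronger signal than the reported index
SNP. The package quantifies both effects.

# Association model

Case-control status is regressed on the imputed allelic dosage
(expected coded-allele count in [0, 2]) by maximum-likelihood logistic
regression, fitted with Newton scoring (IRLS), convergence when the
largest coefficient update is below 1e-8 or after 50 iterations.
Regressing the dosage directly, rather than a best-guess genotype,
propagates imputation uncertainty into the standard error. Covariates
are age (years), sex (female indicator), BMI (kg/m^2) and the leading
genotype principal components (three by default), computed from an
LD-pruned variant subset with columns centred at 2p and scaled by
sqrt(2p(1-p)). Tests are two-sided Wald tests, `p = 2 * pnorm(-|b/se|)`,
matching the beta / SE(beta) / P output convention. Non-convergence,
separation (|beta| > 15) and zero-information fits are flagged in a
`code` column rather than raised. Residual stratification is summarised
by the genomic inflation factor `lambda = median(chi^2) / 0.455936`.

# Quality control

Sample cascade, in order (each exclusion carries one reason code and the
cascade is idempotent):

1. call rate < 0.95;
2. duplicates: pairs with PiHat >= 0.95, removing the lower-call-rate
   member (ties: the later sample id);
3. sex discordance between the reported sex and an X-heterozygosity
   proxy (threshold 0.10; real X-chromosome logic is out of scope, the
   synthetic proxy carries the discordance signal);
4. cryptic relatedness: pairs with PiHat > 0.125 (closer than
   third-degree), pruned greedily by removing the sample in the most
   flagged pairs until none remain (ties: lower call rate, then later id).
   The greedy rule is a documented choice — the analysis this package
   reproduces states how many related subjects were removed but not how
   they were chosen.

PiHat is the classic method-of-moments IBD estimate from identity-by-state
counts over LD-pruned common variants (MAF >= 0.05, complete data),
truncated to [0, 1]. Its sampling noise scales as ~1/sqrt(m): with m
variants the unrelated-pair standard deviation is roughly 0.021 (m =
3,000), 0.015 (m = 6,000), 0.012 (m = 9,000). Exceeding the 0.125
threshold by noise must be rare *per cohort*, i.e. across all ~n^2/2
pairs; the worked QC example therefore uses 9,000 free-recombining
variants (a scaled stand-in for a ~140k LD-pruned array subset), which
puts the threshold ~9 sigma out and makes the expected spurious count
negligible. This is why a few hundred simulated variants are fine for
LD machinery but *not* for relatedness QC.

Variant filters, each evaluated on the input data so reasons are
order-stable and can co-occur: missingness > 0.05; folded MAF < 0.01;
Hardy-Weinberg exact p < 1e-6 (genotyped variants only; all samples by
default, controls-only behind a flag — the source analysis does not say
which); for imputed variants, dosage allele frequency < 0.01 or
imputation r^2 < 0.3 (strict: exactly 0.3 is retained). The HWE test is
the conditional-on-allele-counts exact test, two-sided by probability
mass, computed by a stable ratio recurrence and verified exhaustively
against a direct multinomial enumeration for all totals up to 50.

# LD machinery

**Two-locus EM.** Haplotype frequencies for a variant pair are estimated
from unphased hard-called genotypes; only the double heterozygote is
phase-ambiguous and its split is iterated to convergence (frequency
change < 1e-10, max 1,000 iterations; the EM likelihood is checked to be
non-decreasing at every step). Initialisation is the linkage-equilibrium
product with a +1e-6 coupling perturbation, so the symmetric
all-double-heterozygote input deterministically returns the coupling
solution (p_AB >= p_Ab).

**D' confidence bounds.** The multinomial log-likelihood of the 2n
estimated gametes is evaluated over |D'| in {0, 0.001, ..., 1}, margins
fixed at the sample allele frequencies (the unphased-data MLE) and the
sign of D maximised at each grid point. The 90% interval is the set of
grid values within qchisq(0.90, 1)/2 of the maximum. Fixing the margins
is the practical reduction of "maximise over allele frequencies
consistent with the margins": the frequency MLEs of the unphased
likelihood are the observed allele frequencies.

**Gabriel blocks.** Pairs classify as strong LD (ci_low >= 0.70 and
ci_high >= 0.98), recombination (ci_high < 0.90), else uninformative.
A candidate block is a marker interval whose outermost pair is strong
and in which >= 95% of informative pairs are strong; candidates are
accepted greedily by decreasing bp span, skipping overlaps. The
distance-stratified refinements of the Haploview implementation are
deliberately omitted; pairs farther apart than 500 kb (configurable)
are not computed. Dosages are hard-called before EM because the EM is
defined on genotype counts.

**Effective number of tests.** For the K block SNPs,
`n_eff = (sum lambda_k)^2 / sum(lambda_k^2)` over the eigenvalues of the
K x K *correlation* matrix of dosages. The source analysis says
"covariance matrix" of standardized genotypes — for standardized columns
the two coincide, and correlation makes n_eff invariant to allele coding,
so correlation is used and documented. Adjusted p-values are
`p_adj = min(1, p * n_eff)`, the exact equivalent of testing at
alpha / n_eff. The "best SNP" of a block is the smallest-p SNP with
r^2 >= 0.3 to the index (ties: closer bp, then lexicographic id); the
0.3 eligibility default is permissive relative to observed practice and
configurable. Exact status takes precedence: no locus is both exact and
local. Index SNPs absent from the data, or strand-ambiguous (A/T, C/G)
with MAF in [0.4, 0.6], are `untested`.

# Replication power

Power for replicating a reported per-allele OR uses the allelic Wald
log-OR model at a one-sided alpha (replication requires the same
direction): control risk-allele frequency p0, case frequency
p1 = p0 OR / (1 + p0(OR - 1)), variance
1/(2 n1 p1) + 1/(2 n1 (1-p1)) + 1/(2 n0 p0) + 1/(2 n0 (1-p0)), power
Phi(ln OR / sqrt(var) - z_{1-alpha}). At OR = 1 this is exactly alpha.
A simulation twin (`power_simulated`) draws allele-count tables and
applies the same one-sided test; the two agree within Monte-Carlo error
across the tested OR x RAF grid. The power figures printed in the
source analysis (83% at OR 1.2 / RAF 0.2; 84% at OR 1.3 / RAF 0.1) are
**not** reproduced by this model (which gives ~0.71 and ~0.78); the
method behind those figures is unstated, so they are checked only for
qualitative ordering (power rises with OR and with n), never anchored.

# The synthetic cohort generator

The generator exists so every stage is testable without external
genotypes; it emulates the *statistical* structure the analysis assumes
and nothing more.

* **Panel LD**: within a block, each haplotype carries one latent
  ancestry uniform `u`; site j (target frequency p_j) copies the
  ancestral allele `1(u < p_j)` with probability `within_block_ld`, else
  draws Bernoulli(p_j) independently. Marginals are exact; at copy
  probability 1 block columns are nested sets, so every realised
  within-block |D'| is 1; blocks are mutually independent (free
  recombination). A template-with-flips scheme was considered and
  rejected: its zero-flip limit is monomorphic, which contradicts the
  |D'| = 1 target.
* **Finite-panel vs generative draws**: summing two haplotypes resampled
  from a finite panel (the default) silently creates *true* relatedness
  between samples that share a panel haplotype — detectable by IBD at
  cohort scale. Cohort-sized worlds therefore use `draw = "generative"`,
  which draws fresh haplotypes from the generating process (infinite
  panel). This distinction matters only when relatedness QC is in play.
* **Phenotypes**: logit P(case) = intercept + sum log(OR_j) x risk
  dosage_j + 0.03 age - 0.10 female + 0.02 BMI (defaults; all
  configurable). The intercept is a free parameter (the underlying
  disease prevalence is not stated anywhere authoritative); the default
  -3.0 yields a ~30% pre-ascertainment case rate, appropriate for a
  clinic-enriched diabetes study base. Ascertainment selects exactly
  n_cases and n_controls from an oversampled genotype pool and errors
  with advice to change the intercept when a quota cannot be met.
* **Imputation noise**: d = 2p + r(g - 2p) + e, r = sqrt(r2), e ~ N(0,
  (1 - r2) Var(g)), clipped to [0, 2]; the realised corr(d, g)^2
  converges to the target r2. Clipping slightly biases extreme
  frequencies; tests use mid-range MAF.
* **Flaws**: duplicates are exact copies under new ids; sex discordance
  flips the reported sex against a simulated X-heterozygosity proxy
  (females ~ N(0.22, 0.03), males ~ N(0.02, 0.008)); a planted relative
  has a fraction `related_pihat` of its variants overwritten by its
  partner's genotypes, giving expected PiHat equal to that fraction;
  HWE violations are all-heterozygote columns. All categories are
  disjoint and returned in a truth ledger.
* **Seeds**: one master seed; every stage derives its own seed by
  hashing the stage label (`derive_seed`), so runs are bit-reproducible
  and stages are insertion-stable.

**What a green test does not establish.** The generator has no
coalescent realism: no recombination gradients within blocks, no
admixture tracts, no allele-frequency spectrum matching, no genotyping
batch effects, no X chromosome. Tests on it validate the *algorithms*
(QC logic, EM, block construction, corrections, calibration), not the
biology of any real cohort.

# The QC worked example

`qc_cascade_example()` builds the canonical flawed cohort: 1,821
ascertained samples (1,061 cases / 760 controls — the pre-QC split is
not stated in the source analysis, this one reduces to 1,035/740-scale
after exclusions) plus one appended duplicate = 1,822; 13 sex-discordant
and 33 related samples (target PiHat 0.5), all disjoint. At default
thresholds the cascade removes exactly 1 + 13 + 33 = 47 and retains
1,775. Runtime is ~1.5-2 minutes single-threaded, dominated by the
all-pairs PiHat matrix at 9,000 variants.

# Numerical choices and degenerate inputs

* HWE exact test: ratio recurrence in log space; monomorphic counts
  return p = 1; all-zero counts error.
* EM: monomorphy is judged on allele frequency (an all-heterozygote
  column is polymorphic); margin-degenerate pairs are uninformative.
* PiHat: moment equations solved elementwise, components clamped to
  [0, 1] and renormalised; estimator requires >= 200 informative
  variants and errors below that.
* IRLS: singular information or non-finite updates flag `degenerate`;
  |beta| > 15 flags `separation`; no Firth correction (flagging, not
  penalising, matches the reproduced analysis which gives no indication
  of penalised fits).
* PCA: k must not exceed the numerical rank; missing dosages are
  mean-imputed (zero after centring).
* Coordinates: VCF-style 1-based inclusive internally; BED output is
  0-based half-open. Fixed numeric formats in writers: 4 decimals for
  frequencies/beta/SE, scientific with 2 significant digits for p.

# Known limitations

* Gabriel blocks omit the Haploview distance-stratified CI dialect.
* The relatedness-pruning tie-break is a package convention.
* Imputation noise is linear-Gaussian attenuation, not a posterior from
  a real imputation model.
* The power model is allelic; genotype-level (dominance) models and
  winner's-curse corrections are out of scope.
* Multi-allelic VCF records are counted and skipped, not split.
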
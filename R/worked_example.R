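#' The sample-QC cascade worked example
#'
#' Builds the canonical flawed synthetic cohort — 1,821 ascertained samples
#' (1,061 cases, 760 controls) plus one appended duplicate = 1,822 total,
#' with 13 sex-discordant samples and 33 samples related to a retained
#' partner at target PiHat 0.5, all categories disjoint — and runs the
#' sample-level QC cascade at default thresholds (duplicate PiHat >= 0.95,
#' relatedness PiHat > 0.125). Genotypes are 9,000 free-recombining
#' variants drawn generatively (a scaled-down stand-in for a ~140k
#' LD-pruned autosomal subset; the scale keeps the spurious-relatedness
#' tail negligible across the ~1.66M sample pairs, see the methods
#' vignette).
#'
#' With the planted flaw structure the cascade removes 1 + 13 + 33 = 47
#' samples, retaining 1,775.
#'
#' @param seed master seed.
#' @param n_variants number of free-recombining variants.
#' @return list: `n_input`, `n_retained`, `report` (a [qc_report()]),
#'   `ledger` (planted flaws).
#' @export
qc_cascade_example <- function(seed = 1L, n_variants = 9000L) {
  panel <- simulate_panel(n_blocks = n_variants, snps_per_block = 1L,
                          n_haplotypes = 50L, within_block_ld = 1,
                          maf_range = c(0.1, 0.5),
                          seed = derive_seed(seed, "qc_example_panel"),
                          block_gap_bp = 2000)
  cfg <- cohort_config(
    n_cases = 1061L, n_controls = 760L, seed = seed,
    flaw_spec = flaw_spec(n_duplicates = 1L, n_sex_discordant = 13L,
                          n_related = 33L, related_pihat = 0.5))
  coh <- simulate_cohort(panel, cfg, pool_factor = 2.5, draw = "generative")
  q <- sample_qc(coh$genotypes, coh$samples)
  list(n_input = nrow(coh$genotypes$dosages),
       n_retained = length(q$retained),
       report = q$report, ledger = coh$ledger)
}
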
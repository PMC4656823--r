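test_that("harmonize_alleles orients risk alleles across strand and coding", {
  # A2 carries the risk allele -> flip
  expect_equal(harmonize_alleles("G", "C", "G", maf = 0.2)$multiplier, -1)
  # opposite-strand match: risk A vs study T/C (complement of A/G)
  h <- harmonize_alleles("A", "T", "C", maf = 0.2)
  expect_equal(h$multiplier, 1)
  expect_false(h$ambiguous)
  # palindromic A/T at intermediate frequency is untestable
  amb <- harmonize_alleles("A", "A", "T", maf = 0.48)
  expect_true(amb$ambiguous)
  expect_true(is.na(amb$multiplier))
  # palindromic but frequency-resolvable
  expect_equal(harmonize_alleles("C", "C", "G", maf = 0.1)$multiplier, 1)
  expect_error(harmonize_alleles("A", "C", "G", maf = 0.2), "incompatible")
})

test_that("classify_exact applies the joint p-and-direction rule", {
  # TCF7L2-style row: study codes the non-risk allele, beta negative,
  # reported risk allele on the other strand of the coding -> consistent
  h <- harmonize_alleles("T", "C", "T", maf = 0.33)
  ex <- classify_exact(p = 1.52e-8, beta = -0.466, multiplier = h$multiplier,
                       reported_or = 1.37)
  expect_true(ex$exact)
  expect_true(ex$consistent)

  # both conditions are required
  expect_false(classify_exact(0.049, 0.2, -1, 1.3)$exact) # wrong direction
  expect_false(classify_exact(0.051, 0.2, 1, 1.3)$exact)  # boundary p
  expect_false(classify_exact(0.01, 0.2, NA_real_, 1.3)$exact) # ambiguous
})

test_that("classify_local adjusts by n_eff and picks the best eligible SNP", {
  block <- data.frame(id = c("rsA", "rsB", "rsC"),
                      p = c(0.269, 0.003, 0.0008),
                      pos = c(100, 300, 900), stringsAsFactors = FALSE)
  # index is rsA (not exact, p = 0.269); rsC has smallest p but weak LD
  lc <- classify_local(block, neff = 3, index_id = "rsA", index_pos = 100,
                       r2_to_index = c(1, 0.929, 0.05))
  expect_equal(lc$status, "local")
  expect_equal(lc$best_snp, "rsB")
  expect_equal(lc$p_adj, min(1, 0.003 * 3))
  expect_equal(lc$r2_to_index, 0.929)

  # single-SNP block with n_eff = 1: identity correction
  one <- data.frame(id = "rsA", p = 0.04, pos = 100)
  lc1 <- classify_local(one, 1, "rsA", 100, r2_to_index = 1)
  expect_equal(lc1$p_adj, 0.04)
  expect_equal(lc1$status, "local")

  # nothing in LD with the index
  lc0 <- classify_local(block, 3, "rsA", 100, r2_to_index = c(0.1, 0.2, 0.1))
  expect_equal(lc0$status, "none")

  # exact precedence: a locus already exact is never also local
  lce <- classify_local(block, 3, "rsA", 100, c(1, 0.9, 0.9),
                        already_exact = TRUE)
  expect_equal(lce$status, "none")

  # p_adj bounds: p <= p_adj <= K * p
  k <- nrow(block)
  ne <- 2.2
  lcb <- classify_local(block, ne, "rsA", 100, c(1, 0.9, 0.9))
  expect_gte(lcb$p_adj, lcb$best_p)
  expect_lte(lcb$p_adj, k * lcb$best_p)
})

test_that("sign_consistency_test is the exact one-sided binomial tail", {
  # the headline count: 76 consistent of 103 ~ 1e-6 at one significant figure
  p <- sign_consistency_test(76, 103)
  expect_gte(p, 0.5e-6)
  expect_lt(p, 1.5e-6)

  expect_equal(sign_consistency_test(5, 5), 0.5^5, tolerance = 1e-12)
  expect_equal(sign_consistency_test(50, 100), binom_tail_oracle(50, 100),
               tolerance = 1e-12)

  # oracle equality across all small totals and spot-checked large ones
  for (n in c(1:40, 250, 1000)) {
    ks <- if (n <= 40) 0:n else unique(round(seq(0, n, length.out = 9)))
    for (k in ks) {
      expect_equal(sign_consistency_test(k, n), binom_tail_oracle(k, n),
                   tolerance = 1e-10)
    }
  }
  expect_error(sign_consistency_test(3, 0), "n_total")
})

test_that("compare_blocks reports spans, fine-mapping and refinement", {
  study <- data.frame(chrom = "1", start_bp = 100L, end_bp = 20100L,
                      first = 1L, last = 5L, n_snps = 5L,
                      members = "s1,s2,s3", stringsAsFactors = FALSE)
  ref <- data.frame(chrom = "1", start_bp = 50L, end_bp = 60050L,
                    first = 1L, last = 9L, n_snps = 9L,
                    members = "s1,s2,s3,s4", stringsAsFactors = FALSE)
  assoc <- data.frame(id = c("s1", "s2", "s3"), p = c(0.04, 0.001, 0.2),
                      stringsAsFactors = FALSE)
  cb <- compare_blocks(study, ref, "s1", 150, assoc)
  expect_equal(cb$study_span, 20000)
  expect_equal(cb$ref_span, 60000)
  expect_true(cb$fine_mapped)
  expect_true(cb$refined) # s2 beats the index p
  expect_equal(cb$best_snp, "s2")

  # equal spans are not fine-mapped (strict inequality)
  cb2 <- compare_blocks(study, study, "s1", 150, assoc)
  expect_false(cb2$fine_mapped)

  # index outside any block: span 0, single-marker resolution
  cb3 <- compare_blocks(study, ref, "s9", 999999, assoc)
  expect_equal(cb3$study_span, 0)
  expect_false(cb3$refined)
})

test_that("transfer_calls keeps exact and local disjoint and flags untested", {
  set.seed(51)
  panel <- simulate_panel(4, 6, 300, within_block_ld = 0.95,
                          maf_range = c(0.2, 0.5), seed = 52)
  cfg <- cohort_config(n_cases = 400, n_controls = 400, seed = 53,
                       causal_loci = data.frame(variant = 3, or = 1.9),
                       covariate_effects = c(age = 0, sexF = 0, bmi = 0),
                       intercept = -0.8)
  coh <- simulate_cohort(panel, cfg, draw = "generative")
  g <- coh$genotypes
  assoc <- assoc_scan(g, coh$samples, covariate_cols = character(0))
  pl <- pair_ld_table(g)
  blocks <- gabriel_blocks(pl, g$variants$pos, variant_ids_ = g$variants$id)
  v <- g$variants
  catalog <- data.frame(
    SNP = c(v$id[3],   # causal itself: expect exact
            v$id[4],   # same block as causal: exact or local
            v$id[15],  # null block: none (or untested if ambiguous)
            "rs_absent"),
    CHR = "1", BP = c(v$pos[c(3, 4, 15)], 1),
    RISK_ALLELE = c(v$A1[3], v$A1[4], v$A1[15], "A"),
    REPORTED_OR = c(1.9, 1.9, 1.2, 1.2),
    PANEL = "EUR", GENE = NA, stringsAsFactors = FALSE)
  calls <- transfer_calls(catalog, assoc, g, blocks)
  expect_equal(nrow(calls), 4)
  expect_equal(calls$status[calls$snp == "rs_absent"], "untested")
  expect_equal(calls$status[1], "exact")
  expect_true(all(calls$status %in% c("exact", "local", "none", "untested")))
  # p_adj >= best_p whenever both are defined
  both <- !is.na(calls$p_adj) & !is.na(calls$best_p)
  expect_true(all(calls$p_adj[both] >= calls$best_p[both]))
})
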
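test_that("simulate_panel is deterministic and satisfies its invariants", {
  p1 <- simulate_panel(3, 8, 100, within_block_ld = 0.8, seed = 99)
  p2 <- simulate_panel(3, 8, 100, within_block_ld = 0.8, seed = 99)
  expect_identical(p1, p2)
  expect_true(all(diff(p1$positions) > 0))
  expect_true(all(diff(p1$block_assignment) >= 0))
  cnt <- colSums(p1$haplotypes)
  poly <- cnt > 0 & cnt < nrow(p1$haplotypes)
  expect_true(all(poly | p1$monomorphic))
  expect_error(simulate_panel(2, 2, 10, 0.5, maf_range = c(0.2, 0.2 + 1e-12)),
               "degenerate")
})

test_that("within_block_ld = 1 gives |D'| = 1 for all within-block pairs", {
  p <- simulate_panel(2, 6, 200, within_block_ld = 1,
                      maf_range = c(0.15, 0.5), seed = 7)
  H <- p$haplotypes
  for (b in 1:2) {
    cols <- which(p$block_assignment == b & !p$monomorphic)
    for (a in seq_along(cols)[-length(cols)]) {
      for (bb in (a + 1):length(cols)) {
        ld <- hap_ld(H[, cols[a]], H[, cols[bb]])
        expect_equal(ld$dprime, 1, tolerance = 1e-12)
      }
    }
  }
})

test_that("cross-block r2 matches the 1/n_haplotypes sampling level", {
  # free recombination between blocks: E[r2] of independent loci estimated
  # from nh haplotypes is ~ 1/nh; averaged over 10 seeds x 100 pairs
  nh <- 100
  seed_means <- vapply(1:10, function(s) {
    p <- simulate_panel(2, 10, nh, within_block_ld = 1,
                        maf_range = c(0.2, 0.5), seed = s)
    H <- p$haplotypes
    i <- which(p$block_assignment == 1 & !p$monomorphic)
    j <- which(p$block_assignment == 2 & !p$monomorphic)
    pairs <- expand.grid(i = i, j = j)
    mean(mapply(function(a, b) hap_ld(H[, a], H[, b])$r2,
                pairs$i, pairs$j))
  }, numeric(1))
  mc_se <- sd(seed_means) / sqrt(length(seed_means))
  expect_lt(abs(mean(seed_means) - 1 / nh), 3 * mc_se + 1e-4)
})

test_that("simulate_genotypes draws from the panel correctly", {
  p <- simulate_panel(1, 10, 60, within_block_ld = 0.3,
                      maf_range = c(0.25, 0.35), seed = 3)
  g1 <- simulate_genotypes(p, 50, seed = 5)
  g2 <- simulate_genotypes(p, 50, seed = 5)
  expect_identical(g1, g2)
  expect_true(all(g1$dosages %in% 0:2))

  # single sample
  g <- simulate_genotypes(p, 1, seed = 1)
  expect_equal(nrow(g$dosages), 1)

  # monomorphic panel column stays constant in genotypes
  p$haplotypes[, 4] <- 1L
  gm <- simulate_genotypes(p, 30, seed = 2)
  expect_true(all(gm$dosages[, 4] == 2))

  # sample allele frequency within 4 binomial SE of the panel frequency
  f_panel <- mean(p$haplotypes[, 1])
  n <- 5000
  gs <- simulate_genotypes(p, n, seed = 8)
  f_samp <- mean(gs$dosages[, 1]) / 2
  se <- sqrt(f_panel * (1 - f_panel) / (2 * n))
  expect_lt(abs(f_samp - f_panel), 4 * se)
})

test_that("generative draws preserve LD structure without panel reuse", {
  p <- simulate_panel(2, 6, 100, within_block_ld = 1,
                      maf_range = c(0.25, 0.45), seed = 21)
  g <- simulate_genotypes(p, 400, seed = 4, draw = "generative")
  em <- two_locus_em(g$dosages[, 1], g$dosages[, 2])
  expect_gt(em$d_prime, 0.95) # within-block LD carried over
  em_x <- two_locus_em(g$dosages[, 1], g$dosages[, 8])
  expect_lt(em_x$r2, 0.1) # cross-block independence
})

test_that("simulate_phenotypes ascertains exact counts and validates input", {
  p <- simulate_panel(1, 5, 80, within_block_ld = 0.5, seed = 2)
  pool <- simulate_genotypes(p, 600, seed = 3)
  cfg <- cohort_config(n_cases = 100, n_controls = 150, seed = 10,
                       intercept = -2)
  ph <- simulate_phenotypes(pool, cfg)
  expect_equal(sum(ph$samples$status == 1), 100)
  expect_equal(sum(ph$samples$status == 0), 150)
  expect_equal(nrow(ph$samples), 250)
  ph2 <- simulate_phenotypes(pool, cfg)
  expect_identical(ph, ph2)

  expect_error(cohort_config(n_cases = 0, n_controls = 10), "> 0")
  # unattainable case quota -> advice to change the intercept
  cfg_bad <- cohort_config(n_cases = 400, n_controls = 100, seed = 1,
                           intercept = -30)
  expect_error(simulate_phenotypes(pool, cfg_bad), "intercept")
})

test_that("imputation noise attains the target dosage-genotype correlation", {
  dm <- make_indep_dm(10000, 3, maf = c(0.3, 0.3001), seed = 6)

  # r2 = 1 is the identity
  d1 <- apply_imputation_noise(dm, 1, seed = 1)
  expect_equal(d1$dosages, dm$dosages)
  expect_true(all(d1$variants$imputed))

  d <- apply_imputation_noise(dm, 0.3, seed = 2)
  for (j in 1:3) {
    r2 <- cor(d$dosages[, j], dm$dosages[, j])^2
    expect_lt(abs(r2 - 0.3), 0.03)
  }
  expect_true(all(d$dosages >= 0 & d$dosages <= 2))

  # constant column passes through untouched
  dm$dosages[, 2] <- 1
  dc <- apply_imputation_noise(dm, 0.5, seed = 3)
  expect_true(all(dc$dosages[, 2] == 1))

  expect_error(apply_imputation_noise(dm, 0), "imputation_r2")
})

test_that("inject_flaws plants exactly what the ledger says", {
  dm <- make_indep_dm(60, 2500, seed = 9)
  samples <- make_samples(dm, seed = 9)

  # all-zero spec is the identity
  id <- inject_flaws(dm, samples, flaw_spec(), seed = 1)
  expect_identical(id$genotypes, dm)
  expect_identical(id$samples, samples)
  expect_equal(nrow(id$ledger), 0)

  spec <- flaw_spec(n_duplicates = 1, n_sex_discordant = 2, n_related = 1,
                    related_pihat = 0.5, n_missing_variants = 3,
                    missing_rate = 0.5, n_hwe_violations = 2)
  fl <- inject_flaws(dm, samples, spec, seed = 4)
  led <- fl$ledger
  expect_equal(as.integer(table(led$category)[c("duplicate", "sex_discordant",
                                                "related")]), c(1L, 2L, 1L))
  # categories are disjoint
  expect_false(anyDuplicated(led$id[led$category %in%
    c("duplicate", "sex_discordant", "related")]) > 0)

  # duplicate pair is IBS2 everywhere -> PiHat ~ 1
  dup <- led[led$category == "duplicate", ]
  ph <- ibd_pihat(fl$genotypes, dup$id, dup$partner)
  expect_gte(ph, 0.95)

  # sex flip recorded against the proxy
  sx <- led$id[led$category == "sex_discordant"]
  orig <- samples[match(sx, samples$id), ]
  flip <- fl$samples[match(sx, fl$samples$id), ]
  expect_true(all(orig$sex != flip$sex))
  expect_equal(orig$xhet, flip$xhet)

  # hwe violation column is all-heterozygote
  hv <- led$id[led$category == "hwe_violation"]
  expect_true(all(fl$genotypes$dosages[, hv] == 1))

  # demanding more flawed samples than exist fails
  expect_error(inject_flaws(dm, samples, flaw_spec(n_duplicates = 61),
                            seed = 1), "exceed")
})

test_that("planted relatives hit the target PiHat in expectation", {
  est <- vapply(1:20, function(s) {
    dm <- make_indep_dm(40, 1200, seed = 100 + s)
    samples <- make_samples(dm, seed = s)
    fl <- inject_flaws(dm, samples, flaw_spec(n_related = 1,
                                              related_pihat = 0.5), seed = s)
    rel <- fl$ledger[fl$ledger$category == "related", ]
    ibd_pihat(fl$genotypes, rel$id, rel$partner, min_variants = 150L)
  }, numeric(1))
  expect_lt(abs(mean(est) - 0.5), 0.1)
})
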
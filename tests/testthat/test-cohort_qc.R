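test_that("hwe_exact_test matches its stated examples and the oracle", {
  expect_equal(hwe_exact_test(1, 0, 1), 1 / 3, tolerance = 1e-12)
  expect_equal(hwe_exact_test(0, 4, 0), hwe_oracle(0, 4, 0), tolerance = 1e-12)
  # perfect HWE proportions at large n
  expect_gt(hwe_exact_test(2500, 5000, 2500), 0.99)
  # monomorphic -> p = 1; all-zero -> error
  expect_equal(hwe_exact_test(10, 0, 0), 1)
  expect_error(hwe_exact_test(0, 0, 0), "all-zero")
})

test_that("hwe_exact_test equals enumeration oracle on a spread of configs", {
  set.seed(42)
  for (rep in 1:200) {
    n <- sample(1:200, 1)
    nAA <- sample(0:n, 1)
    nAa <- sample(0:(n - nAA), 1)
    naa <- n - nAA - nAa
    expect_equal(hwe_exact_test(nAA, nAa, naa), hwe_oracle(nAA, nAa, naa),
                 tolerance = 1e-9)
  }
})

test_that("PiHat behaves for duplicates, unrelated and half-shared pairs", {
  dm <- make_indep_dm(30, 2500, seed = 3)

  # duplicate rows
  G <- dm$dosages
  G[2, ] <- G[1, ]
  dup <- dosage_matrix(G, dm$variants)
  M <- pihat_matrix(dup)
  expect_gte(M[1, 2], 0.95)
  expect_equal(M[1, 2], M[2, 1]) # symmetric
  expect_equal(unname(diag(M)), rep(1, nrow(G)))

  # unrelated pairs: PiHat < 0.1 in >= 95% of replicates at 5000 variants,
  # with the true generating frequencies supplied
  set.seed(498)
  p_true <- runif(5000, 0.1, 0.5)
  hits <- vapply(1:60, function(s) {
    d <- make_indep_dm(2, 5000, seed = 500 + s, p = p_true)
    ibd_pihat(d, 1, 2, freqs = p_true)
  }, numeric(1))
  expect_gte(mean(hits < 0.1), 0.95)

  # half-genome-shared pair
  d <- make_indep_dm(2, 5000, seed = 77, p = p_true)
  G <- d$dosages
  share <- seq(1, 5000, by = 2)
  G[2, share] <- G[1, share]
  half <- dosage_matrix(G, d$variants)
  ph <- ibd_pihat(half, 1, 2, freqs = p_true)
  expect_lt(abs(ph - 0.5), 0.1)

  expect_error(ibd_pihat(make_indep_dm(2, 100, seed = 1), 1, 2),
               "at least 200")
})

test_that("sample_qc removes planted flaws and nothing else, idempotently", {
  dm <- make_indep_dm(120, 6000, seed = 10)
  samples <- make_samples(dm, seed = 10)

  clean <- sample_qc(dm, samples)
  expect_equal(clean$retained, samples$id)
  expect_equal(nrow(clean$report$samples), 0)

  spec <- flaw_spec(n_duplicates = 1, n_sex_discordant = 2, n_related = 3,
                    related_pihat = 0.5)
  fl <- inject_flaws(dm, samples, spec, seed = 11)
  q <- sample_qc(fl$genotypes, fl$samples)
  expect_equal(length(q$retained), 120 - 2 - 3) # dup extra + planted removed
  tab <- table(q$report$samples$reason)
  expect_equal(as.integer(tab[c("duplicate", "related", "sex_discordant")]),
               c(1L, 3L, 2L))
  # duplicate resolution keeps one member of the pair
  dup <- fl$ledger[fl$ledger$category == "duplicate", ]
  expect_equal(sum(c(dup$id, dup$partner) %in% q$retained), 1)

  # idempotence
  g2 <- fl$genotypes[match(q$retained, sample_ids(fl$genotypes)), ]
  s2 <- fl$samples[match(q$retained, fl$samples$id), ]
  q2 <- sample_qc(g2, s2)
  expect_equal(q2$retained, q$retained)
  expect_equal(nrow(q2$report$samples), 0)
})

test_that("low call-rate samples are excluded first", {
  dm <- make_indep_dm(80, 6000, seed = 12)
  dm$dosages[3, seq_len(400)] <- NA # call rate 1 - 400/6000 < 0.95? no: 0.933
  samples <- make_samples(dm, seed = 12)
  q <- sample_qc(dm, samples)
  expect_false(sample_ids(dm)[3] %in% q$retained)
  expect_equal(q$report$samples$reason[q$report$samples$id ==
                                         sample_ids(dm)[3]], "low_call_rate")
})

test_that("variant_qc applies each filter with documented boundaries", {
  dm <- make_indep_dm(1000, 8, maf = c(0.2, 0.4), seed = 20)
  v <- dm$variants
  G <- dm$dosages

  G[seq_len(60), 1] <- NA          # missingness 0.06 > 0.05
  G[, 2] <- rbinom(1000, 2, 0.004) # MAF below 0.01
  G[, 3] <- 1                      # extreme HWE violation
  v$imputed[4:6] <- TRUE
  v$imp_r2[4] <- 0.29              # excluded (strict <)
  v$imp_r2[5] <- 0.30              # retained at the boundary
  v$imp_r2[6] <- 0.95
  G[, 6] <- pmin(2, rbinom(1000, 2, 0.003) * 1.0) # dosage freq < 0.01
  dm2 <- dosage_matrix(G, v)

  q <- variant_qc(dm2, qc_thresholds())
  rep <- q$report$variants
  expect_true(all(c("missingness") %in% rep$reason[rep$id == v$id[1]]))
  expect_true("maf" %in% rep$reason[rep$id == v$id[2]])
  expect_true("hwe" %in% rep$reason[rep$id == v$id[3]])
  expect_true("imp_r2" %in% rep$reason[rep$id == v$id[4]])
  expect_false(v$id[5] %in% rep$id)
  expect_true("dosage_freq" %in% rep$reason[rep$id == v$id[6]])
  expect_true(v$id[7] %in% q$retained && v$id[8] %in% q$retained)

  # retained + excluded = input (reasons may repeat per variant)
  expect_equal(sort(union(q$retained, unique(rep$id))), sort(v$id))

  # clean input is the identity
  qc <- variant_qc(dm, qc_thresholds())
  expect_equal(qc$retained, variant_ids(dm))
  expect_equal(nrow(qc$report$variants), 0)
})

test_that("HWE filtering skips imputed variants and respects controls-only", {
  dm <- make_indep_dm(600, 4, maf = c(0.3, 0.4), seed = 30)
  v <- dm$variants
  G <- dm$dosages
  G[, 1] <- 1                 # genotyped violation -> excluded
  v$imputed[2] <- TRUE
  v$imp_r2[2] <- 0.9
  G[, 2] <- 1                 # imputed: HWE not tested -> retained
  dm2 <- dosage_matrix(G, v)
  q <- variant_qc(dm2, qc_thresholds())
  expect_false(v$id[1] %in% q$retained)
  expect_true(v$id[2] %in% q$retained)

  # controls-only mode uses the control subset
  samples <- make_samples(dm2, seed = 30)
  thr <- qc_thresholds(hwe_controls_only = TRUE)
  expect_error(variant_qc(dm2, thr), "sample table")
  q2 <- variant_qc(dm2, thr, samples)
  expect_false(v$id[1] %in% q2$retained)
})
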
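test_that("logistic dosage fit matches the closed-form 2x2 log-OR", {
  # cases: 40 exposed / 60 unexposed; controls: 20 / 80
  d <- c(rep(1, 40), rep(0, 60), rep(1, 20), rep(0, 80))
  y <- c(rep(1, 100), rep(0, 100))
  fit <- logistic_dosage_fit(d, NULL, y)
  expect_equal(fit$beta, log((40 * 80) / (60 * 20)), tolerance = 1e-6)
  expect_equal(fit$se, sqrt(1 / 40 + 1 / 60 + 1 / 20 + 1 / 80),
               tolerance = 1e-6)
  expect_equal(fit$p, 2 * pnorm(-abs(fit$beta / fit$se)), tolerance = 1e-12)
  expect_equal(fit$code, "ok")
  expect_equal(fit$n_used, 200)
})

test_that("allele recoding flips beta and frequency, leaves p unchanged", {
  set.seed(5)
  n <- 800
  d <- rbinom(n, 2, 0.3) + runif(n, -0.1, 0.1)
  d <- pmin(pmax(d, 0), 2)
  cov <- cbind(age = rnorm(n, 50, 8))
  y <- rbinom(n, 1, plogis(-0.5 + 0.4 * d))
  f1 <- logistic_dosage_fit(d, cov, y)
  f2 <- logistic_dosage_fit(2 - d, cov, y)
  expect_equal(f1$beta, -f2$beta, tolerance = 1e-6)
  expect_equal(f1$p, f2$p, tolerance = 1e-8)
  expect_equal(f1$a1_freq, 1 - f2$a1_freq, tolerance = 1e-12)
})

test_that("degenerate fits are flagged, not crashed", {
  y <- rep(c(0, 1), 50)
  expect_equal(logistic_dosage_fit(rep(1, 100), NULL, y)$code, "degenerate")
  # perfect separation
  d <- c(rep(0, 50), rep(2, 50))
  ys <- c(rep(0, 50), rep(1, 50))
  fit <- logistic_dosage_fit(d, NULL, ys)
  expect_true(fit$code %in% c("separation", "nonconverged", "degenerate"))
  # missing dosages reduce n_used
  d2 <- rbinom(100, 2, 0.4)
  d2[1:10] <- NA
  expect_equal(logistic_dosage_fit(d2, NULL, y)$n_used, 90)
})

test_that("null fits are well calibrated", {
  set.seed(11)
  n <- 2000
  z <- vapply(1:200, function(i) {
    d <- rbinom(n, 2, 0.3)
    y <- rbinom(n, 1, 0.4)
    fit <- logistic_dosage_fit(d, NULL, y)
    abs(fit$beta / fit$se)
  }, numeric(1))
  expect_gte(mean(z < 3), 0.99)
})

test_that("genomic inflation follows its definition", {
  expect_equal(genomic_inflation(rep(0.455936, 200)), 1, tolerance = 1e-6)
  x <- rchisq(10000, 1)
  expect_equal(genomic_inflation(2 * x), 2 * genomic_inflation(x),
               tolerance = 1e-12)
  set.seed(3)
  expect_lt(abs(genomic_inflation(rchisq(10000, 1)) - 1), 0.03)
  expect_warning(genomic_inflation(rchisq(50, 1)), "fewer than 100")
})

test_that("ld_prune drops exactly the correlated later variants", {
  set.seed(8)
  n <- 300
  base <- rbinom(n, 2, 0.4)
  G <- cbind(base, base, rbinom(n, 2, 0.3), rbinom(n, 2, 0.2))
  storage.mode(G) <- "numeric"
  rownames(G) <- sprintf("S%03d", 1:n)
  dm <- dosage_matrix(G, data.frame(id = paste0("v", 1:4), chrom = "1",
                                    pos = 1:4 * 1000, A1 = "A", A2 = "C"))
  kept <- ld_prune(dm, window = 4, step = 2, r2_max = 0.5)
  expect_equal(kept, c("v1", "v3", "v4")) # duplicate pair -> one retained

  # mutually independent variants are untouched
  dmi <- make_indep_dm(400, 30, seed = 9)
  expect_equal(ld_prune(dmi, window = 10, step = 5, r2_max = 0.5),
               variant_ids(dmi))

  # post-hoc: no retained pair within a window exceeds the threshold
  p <- simulate_panel(20, 10, 150, within_block_ld = 0.9, seed = 10)
  g <- simulate_genotypes(p, 300, seed = 11)
  kept2 <- ld_prune(g, window = 20, step = 5, r2_max = 0.3)
  idx <- match(kept2, variant_ids(g))
  for (w in seq(1, length(idx) - 1)) {
    upper <- min(w + 19, length(idx))
    if (upper <= w) next
    r2 <- cor(g$dosages[, idx[w:upper], drop = FALSE])^2
    expect_true(all(r2[upper.tri(r2)] <= 0.3 + 1e-9))
  }
})

test_that("genotype PCA separates structured populations", {
  set.seed(12)
  n <- 150
  m <- 400
  p1 <- runif(m, 0.1, 0.9)
  shift <- ifelse(runif(m) < 0.5, 0.25, -0.25)
  p2 <- pmin(pmax(p1 + shift, 0.05), 0.95)
  G <- rbind(
    matrix(rbinom(n * m, 2, rep(p1, each = n)), n, m),
    matrix(rbinom(n * m, 2, rep(p2, each = n)), n, m))
  storage.mode(G) <- "numeric"
  rownames(G) <- sprintf("S%03d", seq_len(2 * n))
  dm <- dosage_matrix(G, data.frame(id = sprintf("v%04d", 1:m), chrom = "1",
                                    pos = 1:m * 1000, A1 = "A", A2 = "C"))
  pca <- genotype_pca(dm, k = 3)
  pop <- rep(c(0, 1), each = n)
  expect_gt(abs(cor(pca$scores[, 1], pop)), 0.9)
  expect_true(all(diff(pca$eigenvalues) <= 1e-9))

  # duplicated samples get identical coordinates
  G2 <- G
  G2[2, ] <- G2[1, ]
  dm2 <- dosage_matrix(G2, dm$variants)
  pca2 <- genotype_pca(dm2, k = 2)
  expect_equal(pca2$scores[1, ], pca2$scores[2, ], tolerance = 1e-8)
})

test_that("homogeneous-population eigenvalues stay within the random bulk", {
  dm <- make_indep_dm(200, 1000, maf = c(0.1, 0.5), seed = 13)
  pca <- genotype_pca(dm, k = 3)
  # Marchenko-Pastur upper edge for n/m aspect ratio, x1.5 tolerance
  edge <- (1 + sqrt(200 / 1000))^2
  expect_lt(pca$eigenvalues[1], 1.5 * edge)
  expect_error(genotype_pca(dm, k = 300), "exceeds")
})

test_that("assoc_scan recovers a planted effect and reports lambda", {
  p <- simulate_panel(30, 1, 400, within_block_ld = 1,
                      maf_range = c(0.2, 0.5), seed = 14, block_gap_bp = 1e6)
  cfg <- cohort_config(n_cases = 300, n_controls = 300, seed = 15,
                       causal_loci = data.frame(variant = 5, or = 2.0),
                       covariate_effects = c(age = 0, sexF = 0, bmi = 0),
                       intercept = -1.2)
  coh <- simulate_cohort(panel = p, config = cfg, draw = "generative")
  res <- assoc_scan(coh$genotypes, coh$samples)
  expect_equal(nrow(res), 30)
  expect_lt(res$p[5], 0.01)
  lam <- attr(res, "lambda_gc")
  expect_true(is.finite(lam) && lam > 0)
})
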
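# Shared fixture builders. Everything is generated in code at test time;
# sizes are scaled down from the analysis the package targets and noted
# where a test depends on them.

# Plain dosage_matrix of independent binomial genotypes (infinite panel).
make_indep_dm <- function(n, m, maf = c(0.1, 0.5), seed = 1,
                          chrom = "1", pos_step = 10000L, p = NULL) {
  set.seed(seed)
  if (is.null(p)) p <- runif(m, maf[1], maf[2])
  G <- matrix(rbinom(n * m, 2, rep(p, each = n)), n, m)
  storage.mode(G) <- "numeric"
  rownames(G) <- sprintf("S%05d", seq_len(n))
  dosage_matrix(G, data.frame(
    id = sprintf("snp%05d", seq_len(m)), chrom = chrom,
    pos = seq_len(m) * pos_step, A1 = "A", A2 = "G",
    stringsAsFactors = FALSE))
}

# Minimal sample table consistent with a dosage_matrix (sexes concordant
# with the X-heterozygosity proxy).
make_samples <- function(dm, seed = 1, case_frac = 0.5) {
  set.seed(seed)
  n <- nrow(dm$dosages)
  sex <- ifelse(runif(n) < 0.59, "F", "M")
  data.frame(
    id = sample_ids(dm),
    status = as.integer(runif(n) < case_frac),
    age = round(rnorm(n, 54, 10), 1),
    sex = sex,
    bmi = round(rnorm(n, 26.3, 4.5), 1),
    xhet = ifelse(sex == "F", 0.22, 0.02),
    stringsAsFactors = FALSE)
}

# Independent oracle for the HWE exact test: direct multinomial evaluation
# with choose()/lgamma, no recurrence shared with the implementation.
hwe_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  n_A <- 2 * n_AA + n_Aa
  rare <- min(n_A, 2 * n - n_A)
  if (rare == 0) return(1)
  hets <- seq(rare %% 2, rare, by = 2)
  logp <- vapply(hets, function(h) {
    naa <- (rare - h) / 2
    nAA <- n - h - naa
    lgamma(n + 1) - lgamma(nAA + 1) - lgamma(h + 1) - lgamma(naa + 1) +
      h * log(2)
  }, numeric(1))
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  obs <- pr[match(n_Aa, hets)]
  min(1, sum(pr[pr <= obs * (1 + 1e-12)]))
}

# Independent oracle for the one-sided binomial tail at 1/2.
binom_tail_oracle <- function(k, n) {
  sum(exp(lchoose(n, k:n) - n * log(2)))
}

# Grid-search oracle for the two-locus EM: genotype log-likelihood over a
# fine grid of D with margins fixed at the sample allele frequencies
# (the unphased-data MLE margins).
em_grid_oracle <- function(g1, g2, step = 0.001) {
  p_a <- mean(g1) / 2
  p_b <- mean(g2) / 2
  tab <- matrix(0, 3, 3)
  for (i in 0:2) for (j in 0:2) tab[i + 1, j + 1] <- sum(g1 == i & g2 == j)
  dmin <- -min(p_a * p_b, (1 - p_a) * (1 - p_b))
  dmax <- min(p_a * (1 - p_b), (1 - p_a) * p_b)
  best <- -Inf
  for (d in seq(dmin, dmax, by = step)) {
    h <- c(AB = p_a * p_b + d, Ab = p_a * (1 - p_b) - d,
           aB = (1 - p_a) * p_b - d, ab = (1 - p_a) * (1 - p_b) + d)
    h <- pmax(h, 1e-12)
    P <- loctransfer:::two_locus_genotype_probs(h)
    ll <- sum(tab[tab > 0] * log(P[tab > 0]))
    if (ll > best) best <- ll
  }
  best
}

# Haplotype-level D-prime and r2 straight from a phased 0/1 matrix.
hap_ld <- function(h1, h2) {
  pA <- mean(h1); pB <- mean(h2)
  pAB <- mean(h1 == 1 & h2 == 1)
  d <- pAB - pA * pB
  dmax <- if (d >= 0) min(pA * (1 - pB), (1 - pA) * pB)
          else min(pA * pB, (1 - pA) * (1 - pB))
  list(dprime = if (dmax == 0) NA else abs(d) / dmax,
       r2 = d^2 / (pA * (1 - pA) * pB * (1 - pB)))
}
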
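#' Quality-control thresholds
#'
#' Defaults follow standard GWAS practice for an imputed case-control
#' cohort: sample call rate >= 0.95; variant missingness > 0.05, HWE exact
#' p < 1e-6 and MAF < 0.01 excluded; relatedness pruning at PiHat > 0.125
#' (third-degree relatives); imputed variants additionally require dosage
#' allele frequency >= 0.01 and imputation r-squared >= 0.3 (strict
#' inequality: r2 exactly 0.3 is retained).
#'
#' @param sample_call_rate_min minimum per-sample call rate.
#' @param variant_missingness_max maximum per-variant missingness.
#' @param hwe_p_min minimum HWE exact p-value (genotyped variants).
#' @param maf_min minimum minor allele frequency.
#' @param pihat_max maximum tolerated pairwise PiHat.
#' @param duplicate_pihat PiHat at or above which a pair is called duplicate.
#' @param dosage_freq_min minimum folded dosage allele frequency (imputed).
#' @param imp_r2_min minimum imputation r-squared (imputed).
#' @param hwe_controls_only test HWE in controls only (default all samples).
#' @param xhet_female_min X-heterozygosity proxy threshold separating
#'   inferred female (above) from male.
#' @return list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(sample_call_rate_min = 0.95,
                          variant_missingness_max = 0.05,
                          hwe_p_min = 1e-6,
                          maf_min = 0.01,
                          pihat_max = 0.125,
                          duplicate_pihat = 0.95,
                          dosage_freq_min = 0.01,
                          imp_r2_min = 0.3,
                          hwe_controls_only = FALSE,
                          xhet_female_min = 0.10) {
  vals <- c(sample_call_rate_min, variant_missingness_max, hwe_p_min,
            maf_min, pihat_max, duplicate_pihat, dosage_freq_min, imp_r2_min)
  check_that(all(vals >= 0 & vals <= 1), "all thresholds must lie in [0, 1]")
  structure(as.list(environment()), class = "qc_thresholds")
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Conditional-on-allele-counts exact test: all heterozygote counts
#' compatible with the observed allele counts are enumerated, the
#' conditional probability of each is computed, and the p-value is the sum
#' of probabilities not exceeding that of the observed configuration
#' (two-sided by probability mass, the field's convention).
#'
#' Probabilities are computed by the stable ratio recurrence
#' `P(h+2)/P(h) = 4 n_AA(h) n_aa(h) / ((h+2)(h+1))` from the mode, then
#' normalised; this matches direct multinomial evaluation to machine
#' precision for totals in the thousands.
#'
#' @param n_AA,n_Aa,n_aa genotype counts.
#' @return The exact p-value in `(0, 1]`.
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  check_that(all(c(n_AA, n_Aa, n_aa) >= 0), "genotype counts must be >= 0")
  n <- n_AA + n_Aa + n_aa
  check_that(n > 0, "all-zero genotype counts")
  n_a <- 2 * n_aa + n_Aa # rare or not; symmetry handled below
  n_A <- 2 * n_AA + n_Aa
  rare <- min(n_A, n_a)
  if (rare == 0) return(1) # monomorphic: single configuration
  # feasible het counts share the parity of the rare allele count
  hets <- seq(rare %% 2, rare, by = 2)
  # unnormalised log-probabilities via multinomial formula, computed
  # with a ratio recurrence anchored at the smallest feasible het count
  logp <- numeric(length(hets))
  for (k in seq_along(hets)[-1]) {
    h_prev <- hets[k - 1]
    naa_prev <- (rare - h_prev) / 2
    nAA_prev <- n - h_prev - naa_prev
    # moving h -> h + 2 converts one AA and one aa into two hets
    logp[k] <- logp[k - 1] + log(4) + log(naa_prev) + log(nAA_prev) -
      log(h_prev + 2) - log(h_prev + 1)
  }
  p_all <- exp(logp - max(logp))
  p_all <- p_all / sum(p_all)
  h_obs <- n_Aa
  check_that(h_obs %in% hets, "genotype counts inconsistent (parity)")
  p_obs <- p_all[match(h_obs, hets)]
  min(1, sum(p_all[p_all <= p_obs * (1 + 1e-12)]))
}

# Expected IBS-given-IBD sums for the method-of-moments estimator.
ibd_expectation_sums <- function(p) {
  q <- 1 - p
  list(
    s0_ibd0 = sum(2 * p^2 * q^2),
    s1_ibd0 = sum(4 * p^3 * q + 4 * p * q^3),
    s2_ibd0 = sum(p^4 + q^4 + 4 * p^2 * q^2),
    s1_ibd1 = sum(2 * p^2 * q + 2 * p * q^2),
    s2_ibd1 = sum(p^3 + q^3 + p^2 * q + p * q^2)
  )
}

#' Method-of-moments IBD estimation (PiHat)
#'
#' Estimates the proportion of the genome shared identical-by-descent
#' between two samples from identity-by-state counts over LD-pruned,
#' reasonably common variants, using the classic method-of-moments
#' decomposition P(IBD = 0, 1, 2) given population allele frequencies.
#' PiHat = P(IBD=1)/2 + P(IBD=2), truncated to `[0, 1]`.
#'
#' @param genotypes a [dosage_matrix()] restricted to LD-pruned variants
#'   (dosages are hard-called internally).
#' @param i,j sample indices or ids of the pair.
#' @param freqs optional per-variant A1 frequencies; estimated from the data
#'   when omitted.
#' @param min_variants minimum number of informative (complete, MAF >= 0.05)
#'   variants required.
#' @return PiHat in `[0, 1]`.
#' @export
ibd_pihat <- function(genotypes, i, j, freqs = NULL, min_variants = 200L) {
  if (is.character(i)) i <- match(i, sample_ids(genotypes))
  if (is.character(j)) j <- match(j, sample_ids(genotypes))
  M <- pihat_matrix(genotypes[c(i, j), ], freqs = freqs,
                    min_variants = min_variants,
                    freq_from = genotypes)
  M[1, 2]
}

#' All-pairs PiHat matrix
#'
#' Vectorised method-of-moments IBD over every sample pair, computed with
#' genotype-indicator matrix products. Only complete variants with
#' MAF >= 0.05 are used.
#'
#' @param genotypes a [dosage_matrix()] of (near-)hard genotypes.
#' @param freqs optional per-variant A1 frequencies.
#' @param min_variants minimum informative variant count.
#' @param freq_from optional larger `dosage_matrix` from which to estimate
#'   frequencies (used when `genotypes` is a pair subset).
#' @return Symmetric n x n matrix of PiHat values (diagonal 1).
#' @export
pihat_matrix <- function(genotypes, freqs = NULL, min_variants = 200L,
                         freq_from = NULL) {
  G <- hard_call(genotypes)$dosages
  if (is.null(freqs)) {
    src <- if (is.null(freq_from)) G else hard_call(freq_from)$dosages
    freqs <- colMeans(src, na.rm = TRUE) / 2
  }
  keep <- !colAnyNA(G) & fold_maf(freqs) >= 0.05
  if (sum(keep) < min_variants) {
    abort("only %d informative variants for IBD; at least %d required",
          sum(keep), min_variants)
  }
  G <- G[, keep, drop = FALSE]
  p <- freqs[keep]
  m <- ncol(G)
  A0 <- (G == 0) * 1
  A1 <- (G == 1) * 1
  A2 <- (G == 2) * 1
  # IBS via indicator crossproducts; tcrossprod uses symmetric BLAS kernels
  T02 <- tcrossprod(A0, A2)
  IBS0 <- T02 + t(T02)
  IBS2 <- tcrossprod(A0) + tcrossprod(A1) + tcrossprod(A2)
  IBS1 <- m - IBS0 - IBS2
  sums <- ibd_expectation_sums(p)
  # moment equations solved elementwise over the whole pair matrix
  P0 <- clamp(IBS0 / sums$s0_ibd0, 0, 1)
  P1 <- clamp((IBS1 - P0 * sums$s1_ibd0) / sums$s1_ibd1, 0, 1)
  P2 <- clamp((IBS2 - P0 * sums$s2_ibd0 - P1 * sums$s2_ibd1) / m, 0, 1)
  S <- P0 + P1 + P2
  out <- clamp((P1 / 2 + P2) / S, 0, 1)
  diag(out) <- 1
  dimnames(out) <- list(rownames(G), rownames(G))
  out
}

colAnyNA <- function(x) colSums(is.na(x)) > 0

#' QC report container
#' @param samples data.frame (id, reason) of excluded samples.
#' @param variants data.frame (id, reason) of excluded variants.
#' @return list of class `qc_report` with per-reason counts.
#' @export
qc_report <- function(samples = NULL, variants = NULL) {
  empty <- data.frame(id = character(), reason = character(),
                      stringsAsFactors = FALSE)
  if (is.null(samples)) samples <- empty
  if (is.null(variants)) variants <- empty
  structure(list(
    samples = samples, variants = variants,
    counts = c(table(samples$reason), table(variants$reason))
  ), class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %d samples, %d variants excluded\n",
              nrow(x$samples), nrow(x$variants)))
  if (length(x$counts)) print(x$counts)
  invisible(x)
}

#' Sample-level quality-control cascade
#'
#' Applies, in order: (1) call-rate filter; (2) duplicate detection (pairs
#' with PiHat >= `duplicate_pihat`; the member with the lower call rate is
#' removed, ties broken by removing the later sample id); (3) sex
#' discordance between reported sex and the X-heterozygosity proxy
#' (`xhet` column of the sample table); (4) relatedness pruning: among the
#' remaining samples, repeatedly remove the sample participating in the most
#' pairs with PiHat > `pihat_max` (ties: lower call rate, then later id)
#' until no such pair remains. Each excluded sample carries one reason code;
#' the cascade is idempotent.
#'
#' @param genotypes a [dosage_matrix()].
#' @param samples sample table with columns `id`, `sex` and `xhet`.
#' @param thresholds a [qc_thresholds()].
#' @param min_relatedness_variants minimum pruned variants for the IBD step.
#' @return list with `retained` (sample ids) and `report` (a [qc_report()]).
#' @export
sample_qc <- function(genotypes, samples, thresholds = qc_thresholds(),
                      min_relatedness_variants = 200L) {
  check_that(all(sample_ids(genotypes) %in% samples$id),
             "sample table does not cover all genotype rows")
  samples <- samples[match(sample_ids(genotypes), samples$id), ]
  ids <- samples$id
  call_rate <- sample_call_rate(genotypes)
  excl <- data.frame(id = character(), reason = character(),
                     stringsAsFactors = FALSE)
  drop_ids <- function(ids_out, reason) {
    if (length(ids_out)) {
      excl <<- rbind(excl, data.frame(id = ids_out, reason = reason,
                                      stringsAsFactors = FALSE))
    }
  }

  # 1. call rate
  low_cr <- ids[call_rate < thresholds$sample_call_rate_min]
  drop_ids(low_cr, "low_call_rate")
  active <- setdiff(ids, low_cr)

  # PiHat over an LD-pruned subset of the active samples
  g_act <- genotypes[match(active, ids), ]
  pruned <- ld_prune(g_act, window = 50L, step = 5L, r2_max = 0.5)
  M <- pihat_matrix(g_act[, pruned], min_variants = min_relatedness_variants)
  cr <- call_rate[match(active, ids)]
  names(cr) <- active

  # deterministic removal choice within a flagged pair / degree tie set:
  # lower call rate first, then the later sample id (original row order)
  pick_removal <- function(cand) {
    o <- order(cr[cand], -match(cand, ids))
    cand[o[1]]
  }

  # 2. duplicates
  repeat {
    dup <- which(M >= thresholds$duplicate_pihat & upper.tri(M), arr.ind = TRUE)
    if (nrow(dup) == 0) break
    pair <- rownames(M)[dup[1, ]]
    out <- pick_removal(pair)
    drop_ids(out, "duplicate")
    keep <- setdiff(rownames(M), out)
    M <- M[keep, keep, drop = FALSE]
  }
  active <- rownames(M)

  # 3. sex discordance (reported vs X-heterozygosity proxy)
  st <- samples[match(active, samples$id), ]
  inferred <- ifelse(st$xhet >= thresholds$xhet_female_min, "F", "M")
  disc <- st$id[!is.na(st$sex) & inferred != st$sex]
  drop_ids(disc, "sex_discordant")
  active <- setdiff(active, disc)
  M <- M[active, active, drop = FALSE]

  # 4. greedy relatedness pruning
  repeat {
    rel <- M > thresholds$pihat_max & upper.tri(M)
    deg <- rowSums(rel) + colSums(rel)
    if (!any(deg > 0)) break
    cand <- rownames(M)[deg == max(deg)]
    out <- pick_removal(cand)
    drop_ids(out, "related")
    keep <- setdiff(rownames(M), out)
    M <- M[keep, keep, drop = FALSE]
  }
  retained <- ids[ids %in% rownames(M)]
  list(retained = retained, report = qc_report(samples = excl))
}

#' Variant-level quality-control filters
#'
#' Every filter is evaluated on the input data (order-stable); a variant may
#' carry several reason codes. Filters: missingness > threshold; HWE exact
#' p < threshold (genotyped variants only, all samples by default); folded
#' MAF < threshold; for imputed variants additionally folded dosage allele
#' frequency < `dosage_freq_min` or imputation r2 < `imp_r2_min` (strict:
#' r2 exactly at the threshold is retained).
#'
#' @param genotypes a [dosage_matrix()].
#' @param thresholds a [qc_thresholds()].
#' @param samples optional sample table (needed for `hwe_controls_only`).
#' @return list with `retained` (variant ids) and `report` (a [qc_report()]).
#' @export
variant_qc <- function(genotypes, thresholds = qc_thresholds(),
                       samples = NULL) {
  v <- genotypes$variants
  miss <- variant_missingness(genotypes)
  f <- a1_freq(genotypes)
  excl <- data.frame(id = character(), reason = character(),
                     stringsAsFactors = FALSE)
  flag <- function(sel, reason) {
    if (any(sel)) {
      excl <<- rbind(excl, data.frame(id = v$id[sel], reason = reason,
                                      stringsAsFactors = FALSE))
    }
  }

  flag(miss > thresholds$variant_missingness_max, "missingness")
  flag(fold_maf(f) < thresholds$maf_min, "maf")

  hwe_rows <- genotypes$dosages
  if (isTRUE(thresholds$hwe_controls_only)) {
    check_that(!is.null(samples), "hwe_controls_only requires a sample table")
    ctrl <- samples$id[samples$status == 0]
    hwe_rows <- hwe_rows[rownames(hwe_rows) %in% ctrl, , drop = FALSE]
  }
  gh <- round(hwe_rows)
  hwe_p <- rep(NA_real_, ncol(gh))
  for (j in which(!v$imputed)) {
    gj <- gh[, j]
    gj <- gj[!is.na(gj)]
    if (length(gj) == 0) next
    hwe_p[j] <- hwe_exact_test(sum(gj == 2), sum(gj == 1), sum(gj == 0))
  }
  flag(!is.na(hwe_p) & hwe_p < thresholds$hwe_p_min, "hwe")

  imp <- v$imputed
  flag(imp & fold_maf(f) < thresholds$dosage_freq_min, "dosage_freq")
  flag(imp & !is.na(v$imp_r2) & v$imp_r2 < thresholds$imp_r2_min, "imp_r2")

  retained <- setdiff(v$id, unique(excl$id))
  list(retained = retained, report = qc_report(variants = excl))
}
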
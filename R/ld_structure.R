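#' Two-locus haplotype frequency estimation by EM
#'
#' Estimates the four haplotype frequencies (AB, Ab, aB, ab; capital =
#' allele coded 1) from unphased hard genotypes at two loci. All genotype
#' configurations are phase-resolved except the double heterozygote, whose
#' expected split between AB/ab and Ab/aB is iterated to convergence
#' (absolute frequency change < 1e-10, at most 1000 iterations). The EM
#' likelihood is non-decreasing by construction and is checked at every
#' step. Initialisation is the linkage-equilibrium product with a tiny
#' coupling perturbation, so the symmetric all-double-heterozygote case
#' deterministically returns the coupling solution (`p_AB >= p_Ab`).
#'
#' @param g1,g2 integer genotype vectors in `{0, 1, 2}` (dosages are
#'   rounded; NAs dropped pairwise).
#' @return list with `freq` (named numeric: AB, Ab, aB, ab), `d` (raw D),
#'   `d_prime` (|D'|), `r2`, `p_a`, `p_b` (allele-1 frequencies),
#'   `n` (samples used), `loglik`, `iterations`.
#' @export
two_locus_em <- function(g1, g2) {
  ok <- !is.na(g1) & !is.na(g2)
  g1 <- round(g1[ok])
  g2 <- round(g2[ok])
  n <- length(g1)
  check_that(n > 0, "no complete genotype pairs")
  # polymorphism is an allele-frequency property: an all-heterozygote
  # column has zero genotype variance but both alleles at 0.5
  f1 <- mean(g1) / 2
  f2 <- mean(g2) / 2
  check_that(f1 > 0 && f1 < 1 && f2 > 0 && f2 < 1,
             "monomorphic locus: haplotype frequencies uninformative")
  # 3x3 genotype count table, rows g1 = 0,1,2, cols g2 = 0,1,2
  tab <- matrix(0, 3, 3)
  for (i in 0:2) for (j in 0:2) tab[i + 1, j + 1] <- sum(g1 == i & g2 == j)

  p_a <- mean(g1) / 2
  p_b <- mean(g2) / 2
  eps <- 1e-6
  h <- c(AB = p_a * p_b + eps, Ab = p_a * (1 - p_b) - eps,
         aB = (1 - p_a) * p_b - eps, ab = (1 - p_a) * (1 - p_b) + eps)
  h <- clamp(h, 1e-12, 1)
  h <- h / sum(h)

  n_dh <- tab[2, 2] # double heterozygotes
  # haplotype counts contributed by unambiguous genotype cells:
  # cell (i, j) contributes i copies of allele A and j of B across 2 gametes
  fixed <- c(
    AB = 2 * tab[3, 3] + tab[3, 2] + tab[2, 3],
    Ab = 2 * tab[3, 1] + tab[3, 2] + tab[2, 1],
    aB = 2 * tab[1, 3] + tab[1, 2] + tab[2, 3],
    ab = 2 * tab[1, 1] + tab[1, 2] + tab[2, 1]
  )
  loglik <- function(h) {
    P <- two_locus_genotype_probs(h)
    sum(tab[tab > 0] * log(P[tab > 0]))
  }
  ll_old <- loglik(h)
  it <- 0L
  repeat {
    it <- it + 1L
    # E step: split double heterozygotes between the two phase resolutions
    denom <- h["AB"] * h["ab"] + h["Ab"] * h["aB"]
    w <- if (denom > 0) h["AB"] * h["ab"] / denom else 0.5
    cnt <- fixed + n_dh * c(w, 1 - w, 1 - w, w)
    h_new <- cnt / (2 * n)
    delta <- max(abs(h_new - h))
    h <- h_new
    ll_new <- loglik(h)
    if (ll_new < ll_old - 1e-9) {
      abort("EM log-likelihood decreased (%g -> %g)", ll_old, ll_new)
    }
    ll_old <- ll_new
    if (delta < 1e-10 || it >= 1000L) break
  }
  d <- h[["AB"]] - p_a * p_b
  list(freq = h, d = d, d_prime = dprime_from_freq(h),
       r2 = d^2 / (p_a * (1 - p_a) * p_b * (1 - p_b)),
       p_a = p_a, p_b = p_b, n = n, loglik = ll_old, iterations = it)
}

# Genotype-cell probabilities (3x3) from haplotype frequencies under
# random mating; cell (i+1, j+1) = P(g1 = i, g2 = j).
two_locus_genotype_probs <- function(h) {
  hAB <- h[["AB"]]; hAb <- h[["Ab"]]; haB <- h[["aB"]]; hab <- h[["ab"]]
  P <- matrix(0, 3, 3)
  P[1, 1] <- hab^2
  P[1, 2] <- 2 * hab * haB
  P[1, 3] <- haB^2
  P[2, 1] <- 2 * hab * hAb
  P[2, 2] <- 2 * hAB * hab + 2 * hAb * haB
  P[2, 3] <- 2 * haB * hAB
  P[3, 1] <- hAb^2
  P[3, 2] <- 2 * hAb * hAB
  P[3, 3] <- hAB^2
  P
}

# |D'| from haplotype frequencies.
dprime_from_freq <- function(h) {
  p_a <- h[["AB"]] + h[["Ab"]]
  p_b <- h[["AB"]] + h[["aB"]]
  d <- h[["AB"]] - p_a * p_b
  if (p_a <= 0 || p_a >= 1 || p_b <= 0 || p_b >= 1) return(NA_real_)
  dmax <- if (d >= 0) min(p_a * (1 - p_b), (1 - p_a) * p_b)
          else min(p_a * p_b, (1 - p_a) * (1 - p_b))
  if (dmax == 0) return(0)
  abs(d) / dmax
}

# Haplotype frequencies implied by margins (p_a, p_b) and signed D.
freq_from_margins_d <- function(p_a, p_b, d) {
  c(AB = p_a * p_b + d, Ab = p_a * (1 - p_b) - d,
    aB = (1 - p_a) * p_b - d, ab = (1 - p_a) * (1 - p_b) + d)
}

#' Profile-likelihood confidence bounds on |D'|
#'
#' Evaluates the multinomial log-likelihood of the estimated haplotype
#' counts (`2 n` gametes at the supplied frequencies) over a 0.001-step
#' grid of |D'| in `[0, 1]`, with allele frequencies fixed at the sample
#' margins and the likelihood maximised over the sign of D at each grid
#' point. The interval is the set of grid values whose log-likelihood lies
#' within `qchisq(0.90, 1) / 2` of the maximum — the 90% bound convention
#' of the haplotype-block literature.
#'
#' @param freq named haplotype frequencies (AB, Ab, aB, ab).
#' @param n_samples number of diploid samples behind the estimate (>= 10).
#' @return list with `ci_low`, `ci_high`, `d_prime` (point estimate).
#' @export
dprime_ci <- function(freq, n_samples) {
  check_that(n_samples >= 10, "at least 10 samples required for D' bounds")
  check_that(abs(sum(freq) - 1) < 1e-6 && all(freq >= -1e-12),
             "invalid haplotype frequencies")
  p_a <- freq[["AB"]] + freq[["Ab"]]
  p_b <- freq[["AB"]] + freq[["aB"]]
  if (p_a <= 0 || p_a >= 1 || p_b <= 0 || p_b >= 1) {
    abort("margin-degenerate frequencies: |D'| uninformative")
  }
  counts <- 2 * n_samples * freq
  grid <- seq(0, 1, by = 0.001)
  dmax_pos <- min(p_a * (1 - p_b), (1 - p_a) * p_b)
  dmax_neg <- min(p_a * p_b, (1 - p_a) * (1 - p_b))
  ll_vec <- function(d) { # vectorised over signed D
    sum_log <- counts[["AB"]] * log(clamp(p_a * p_b + d, 1e-12, 1)) +
      counts[["Ab"]] * log(clamp(p_a * (1 - p_b) - d, 1e-12, 1)) +
      counts[["aB"]] * log(clamp((1 - p_a) * p_b - d, 1e-12, 1)) +
      counts[["ab"]] * log(clamp((1 - p_a) * (1 - p_b) + d, 1e-12, 1))
    sum_log
  }
  ll <- pmax(ll_vec(grid * dmax_pos), ll_vec(-grid * dmax_neg))
  keep <- ll >= max(ll) - stats::qchisq(0.90, 1) / 2
  list(ci_low = min(grid[keep]), ci_high = max(grid[keep]),
       d_prime = dprime_from_freq(freq))
}

#' Pairwise LD for all variant pairs within a distance
#'
#' Runs [two_locus_em()] and [dprime_ci()] for every variant pair closer
#' than `max_pair_distance_bp` and classifies each pair for the Gabriel
#' block algorithm: `strong_ld` if `ci_low >= 0.70` and `ci_high >= 0.98`;
#' `recombination` if `ci_high < 0.90`; otherwise `uninformative`.
#' Monomorphic or margin-degenerate pairs are `uninformative`.
#'
#' @param genotypes a [dosage_matrix()] (hard-called internally).
#' @param max_pair_distance_bp maximum bp separation of a computed pair.
#' @param strong_ci_low,strong_ci_high,recomb_ci_high Gabriel thresholds.
#' @return data.frame: `id_a, id_b, i, j, dprime, ci_low, ci_high, r2,
#'   class`.
#' @export
pair_ld_table <- function(genotypes, max_pair_distance_bp = 5e5,
                          strong_ci_low = 0.70, strong_ci_high = 0.98,
                          recomb_ci_high = 0.90) {
  g <- hard_call(genotypes)
  v <- g$variants
  m <- nrow(v)
  rows <- list()
  k <- 0L
  for (i in seq_len(max(m - 1, 0))) {
    for (j in (i + 1):m) {
      if (v$chrom[j] != v$chrom[i]) next
      if (v$pos[j] - v$pos[i] > max_pair_distance_bp) break
      em <- tryCatch(two_locus_em(g$dosages[, i], g$dosages[, j]),
                     error = function(e) NULL)
      if (is.null(em)) {
        res <- data.frame(id_a = v$id[i], id_b = v$id[j], i = i, j = j,
                          dprime = NA_real_, ci_low = NA_real_,
                          ci_high = NA_real_, r2 = NA_real_,
                          class = "uninformative", stringsAsFactors = FALSE)
      } else {
        ci <- tryCatch(dprime_ci(em$freq, em$n), error = function(e) NULL)
        cls <- "uninformative"
        lo <- hi <- NA_real_
        if (!is.null(ci)) {
          lo <- ci$ci_low
          hi <- ci$ci_high
          if (lo >= strong_ci_low && hi >= strong_ci_high) cls <- "strong_ld"
          else if (hi < recomb_ci_high) cls <- "recombination"
        }
        res <- data.frame(id_a = v$id[i], id_b = v$id[j], i = i, j = j,
                          dprime = em$d_prime, ci_low = lo, ci_high = hi,
                          r2 = em$r2, class = cls, stringsAsFactors = FALSE)
      }
      k <- k + 1L
      rows[[k]] <- res
    }
  }
  if (k == 0) {
    return(data.frame(id_a = character(), id_b = character(), i = integer(),
                      j = integer(), dprime = numeric(), ci_low = numeric(),
                      ci_high = numeric(), r2 = numeric(), class = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Gabriel confidence-interval haplotype blocks
#'
#' Candidate blocks are marker intervals whose outermost pair is in strong
#' LD and in which at least `informative_frac` of informative pairs
#' (strong LD or recombination) are strong LD. Candidates are accepted
#' greedily by decreasing bp span (ties: leftmost first), skipping any
#' candidate overlapping an accepted block. Blocks have >= 2 markers.
#'
#' @param pairs a [pair_ld_table()] result.
#' @param positions per-variant bp positions (1-based).
#' @param chrom chromosome label for the output.
#' @param variant_ids_ per-variant ids aligned with `positions`.
#' @param informative_frac minimum fraction of informative pairs in strong
#'   LD (default 0.95).
#' @return data.frame of blocks: `chrom, start_bp, end_bp, first, last,
#'   n_snps, members` (comma-joined ids), sorted by position,
#'   non-overlapping.
#' @export
gabriel_blocks <- function(pairs, positions, chrom = "1",
                           variant_ids_ = NULL,
                           informative_frac = 0.95) {
  m <- length(positions)
  if (is.null(variant_ids_)) variant_ids_ <- sprintf("v%04d", seq_len(m))
  empty <- data.frame(chrom = character(), start_bp = integer(),
                      end_bp = integer(), first = integer(), last = integer(),
                      n_snps = integer(), members = character(),
                      stringsAsFactors = FALSE)
  if (m < 2 || nrow(pairs) == 0) return(empty)
  cls <- matrix(NA_character_, m, m)
  cls[cbind(pairs$i, pairs$j)] <- pairs$class

  cands <- list()
  k <- 0L
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      outer_cls <- cls[i, j]
      if (is.na(outer_cls) || outer_cls != "strong_ld") next
      sub <- cls[i:j, i:j]
      sub <- sub[upper.tri(sub)]
      n_strong <- sum(sub == "strong_ld", na.rm = TRUE)
      n_inf <- n_strong + sum(sub == "recombination", na.rm = TRUE)
      if (n_inf == 0 || n_strong / n_inf < informative_frac) next
      k <- k + 1L
      cands[[k]] <- c(i = i, j = j, span = positions[j] - positions[i])
    }
  }
  if (k == 0) return(empty)
  cd <- do.call(rbind, cands)
  cd <- cd[order(-cd[, "span"], cd[, "i"]), , drop = FALSE]
  taken <- rep(FALSE, m)
  out <- list()
  b <- 0L
  for (r in seq_len(nrow(cd))) {
    i <- cd[r, "i"]; j <- cd[r, "j"]
    if (any(taken[i:j])) next
    taken[i:j] <- TRUE
    b <- b + 1L
    out[[b]] <- data.frame(
      chrom = chrom, start_bp = positions[i], end_bp = positions[j],
      first = i, last = j, n_snps = j - i + 1L,
      members = paste(variant_ids_[i:j], collapse = ","),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res[order(res$start_bp), , drop = FALSE]
}

#' Effective number of independent tests (spectral)
#'
#' Computes the correlation matrix of the K dosage columns, its eigenvalues
#' `lambda_1 >= ... >= lambda_K` (numerical negatives above `-1e-10` are
#' clipped to zero), and `n_eff = (sum lambda)^2 / sum(lambda^2)`, which
#' equals K for mutually independent SNPs and 1 for perfectly correlated
#' ones. The correlation (rather than covariance) matrix makes the result
#' invariant to allele coding; with standardized genotypes the two
#' coincide.
#'
#' @param genotypes a [dosage_matrix()] or numeric matrix of the K SNP
#'   columns.
#' @return list of class `neff_result`: `k`, `eigenvalues`, `n_eff`.
#' @export
effective_tests <- function(genotypes) {
  X <- if (inherits(genotypes, "dosage_matrix")) genotypes$dosages else
    as.matrix(genotypes)
  check_that(ncol(X) >= 1, "at least one SNP required")
  sds <- apply(X, 2, stats::sd, na.rm = TRUE)
  if (any(is.na(sds) | sds == 0)) {
    bad <- colnames(X)[which(is.na(sds) | sds == 0)[1]]
    abort("constant dosage column: %s", if (is.null(bad)) "unnamed" else bad)
  }
  C <- stats::cor(X, use = "pairwise.complete.obs")
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  check_that(all(ev > -1e-8), "correlation matrix not PSD")
  ev[ev < 0] <- 0
  structure(list(k = ncol(X), eigenvalues = ev,
                 n_eff = sum(ev)^2 / sum(ev^2)),
            class = "neff_result")
}

#' @export
print.neff_result <- function(x, ...) {
  cat(sprintf("<neff_result> K = %d, n_eff = %.4f\n", x$k, x$n_eff))
  invisible(x)
}
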
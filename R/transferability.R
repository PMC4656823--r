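#' Harmonize a reported risk allele with the study's allele coding
#'
#' Returns `+1` when the study's coded allele A1 is the reported risk
#' allele (directly or as its strand complement), `-1` when A2 is, so that
#' `multiplier * beta` is the log-odds of the risk allele. Strand-ambiguous
#' variants (A/T or C/G) whose study minor allele frequency lies in
#' `[0.4, 0.6]` cannot be oriented reliably and return `NA` with an
#' ambiguity flag.
#'
#' @param risk_allele reported risk allele (single base).
#' @param a1,a2 study coded and other allele.
#' @param maf study folded minor allele frequency (used only for the
#'   ambiguity rule).
#' @return list: `multiplier` (+1, -1 or NA), `ambiguous` (logical).
#' @export
harmonize_alleles <- function(risk_allele, a1, a2, maf = NA_real_) {
  risk_allele <- toupper(risk_allele)
  a1 <- toupper(a1)
  a2 <- toupper(a2)
  palindromic <- a1 == complement_allele(a2)
  if (palindromic && !is.na(maf) && maf >= 0.4 && maf <= 0.6) {
    return(list(multiplier = NA_real_, ambiguous = TRUE))
  }
  mult <- if (risk_allele == a1) 1
    else if (risk_allele == a2) -1
    else if (complement_allele(risk_allele) == a1) 1
    else if (complement_allele(risk_allele) == a2) -1
    else NULL
  if (is.null(mult)) {
    abort("risk allele %s incompatible with study alleles %s/%s",
          risk_allele, a1, a2)
  }
  list(multiplier = mult, ambiguous = FALSE)
}

#' Exact transferability verdict at the index SNP
#'
#' A locus shows exact transferability when the index SNP's association
#' p-value is below `alpha` AND the harmonized effect direction agrees with
#' the originally reported odds ratio (risk-increasing stays
#' risk-increasing).
#'
#' @param p index SNP association p-value.
#' @param beta study log-odds for the study's A1 allele.
#' @param multiplier harmonization multiplier from [harmonize_alleles()].
#' @param reported_or originally reported per-allele OR for the risk allele.
#' @param alpha significance level (default 0.05).
#' @return list: `exact` (logical), `consistent` (logical), `p`.
#' @export
classify_exact <- function(p, beta, multiplier, reported_or, alpha = 0.05) {
  check_that(reported_or > 0, "reported OR must be > 0")
  if (is.na(multiplier) || is.na(p) || is.na(beta)) {
    return(list(exact = FALSE, consistent = NA, p = p))
  }
  consistent <- sign(beta * multiplier) == sign(log(reported_or)) &&
    reported_or != 1 && beta != 0
  list(exact = (p < alpha) && isTRUE(consistent), consistent = consistent,
       p = p)
}

#' Local transferability over an LD block
#'
#' Adjusts each block SNP's p-value for the effective number of independent
#' tests, `p_adj = min(1, p * n_eff)` (equivalent to testing at
#' `alpha / n_eff`), restricts to SNPs in LD with the index
#' (`r2_to_index >= r2_min`), and selects the best SNP as the smallest
#' adjusted p (ties: smaller bp distance to the index, then lexicographic
#' id). The locus is locally transferable when the best adjusted p is
#' below `alpha` and the locus is not already exact.
#'
#' @param block_assoc association results for the block SNPs (data.frame
#'   with `id`, `p`, `pos`).
#' @param neff a [effective_tests()] result (or the n_eff number) computed
#'   on the same SNP set.
#' @param index_id index SNP id.
#' @param index_pos index SNP bp position.
#' @param r2_to_index per-SNP squared correlation with the index, aligned
#'   with `block_assoc` rows.
#' @param alpha significance level.
#' @param r2_min minimum r2 to count as "in LD with the reported SNP".
#' @param already_exact was the locus already called exact?
#' @return list: `status` (`"local"` or `"none"`), `best_snp`, `best_p`,
#'   `p_adj`, `n_eff`, `r2_to_index` (of the best SNP), `reason`.
#' @export
classify_local <- function(block_assoc, neff, index_id, index_pos,
                           r2_to_index, alpha = 0.05, r2_min = 0.3,
                           already_exact = FALSE) {
  n_eff <- if (inherits(neff, "neff_result")) neff$n_eff else as.numeric(neff)
  check_that(n_eff >= 1, "n_eff must be >= 1")
  check_that(nrow(block_assoc) == length(r2_to_index),
             "r2_to_index must align with block_assoc")
  eligible <- !is.na(r2_to_index) & r2_to_index >= r2_min &
    !is.na(block_assoc$p)
  if (!any(eligible)) {
    return(list(status = "none", best_snp = NA_character_, best_p = NA_real_,
                p_adj = NA_real_, n_eff = n_eff, r2_to_index = NA_real_,
                reason = "no SNP in LD with the index"))
  }
  cand <- block_assoc[eligible, , drop = FALSE]
  cand_r2 <- r2_to_index[eligible]
  p_adj <- pmin(1, cand$p * n_eff)
  o <- order(cand$p, abs(cand$pos - index_pos), cand$id)
  best <- o[1]
  status <- if (!already_exact && p_adj[best] < alpha) "local" else "none"
  list(status = status, best_snp = cand$id[best], best_p = cand$p[best],
       p_adj = p_adj[best], n_eff = n_eff, r2_to_index = cand_r2[best],
       reason = if (status == "local") "adjusted p below alpha"
                else if (already_exact) "locus already exact"
                else "best adjusted p not significant")
}

#' One-sided exact binomial sign-consistency test
#'
#' Tests whether the number of loci whose effect direction matches the
#' original report exceeds the coin-flip expectation: the upper binomial
#' tail `P(X >= n_consistent | n_total, 1/2)`, summed exactly.
#'
#' @param n_consistent directionally consistent loci.
#' @param n_total tested loci (>= 1).
#' @return Exact one-sided p-value.
#' @export
sign_consistency_test <- function(n_consistent, n_total) {
  check_that(n_total >= 1, "n_total must be >= 1")
  check_that(n_consistent >= 0 && n_consistent <= n_total,
             "n_consistent must lie in [0, n_total]")
  sum(stats::dbinom(n_consistent:n_total, n_total, 0.5))
}

#' Block-size fine-mapping comparison at an index locus
#'
#' Compares the bp span of the haplotype block containing the index SNP in
#' the study sample against the block in the discovery-ancestry reference
#' panel. An index SNP falling in no block gets span 0 (single-marker
#' resolution). `fine_mapped` requires a strictly smaller study span;
#' `refined` indicates that some other study-block SNP beats the index
#' SNP's p-value.
#'
#' @param study_blocks,ref_blocks block tables from [gabriel_blocks()].
#' @param index_id index SNP id.
#' @param index_pos index SNP bp position.
#' @param study_assoc study association results (`id`, `p`).
#' @return list: `study_span`, `ref_span`, `fine_mapped`, `refined`,
#'   `best_snp`, `best_p`, `index_p`.
#' @export
compare_blocks <- function(study_blocks, ref_blocks, index_id, index_pos,
                           study_assoc) {
  span_at <- function(blocks) {
    if (is.null(blocks) || nrow(blocks) == 0) return(list(span = 0, members = NULL))
    hit <- which(blocks$start_bp <= index_pos & blocks$end_bp >= index_pos)
    if (length(hit) == 0) return(list(span = 0, members = NULL))
    b <- blocks[hit[1], ]
    list(span = b$end_bp - b$start_bp,
         members = strsplit(b$members, ",", fixed = TRUE)[[1]])
  }
  st <- span_at(study_blocks)
  rf <- span_at(ref_blocks)
  index_p <- study_assoc$p[match(index_id, study_assoc$id)]
  best_snp <- NA_character_
  best_p <- NA_real_
  if (!is.null(st$members)) {
    others <- study_assoc[study_assoc$id %in% setdiff(st$members, index_id), ,
                          drop = FALSE]
    others <- others[!is.na(others$p), , drop = FALSE]
    if (nrow(others)) {
      k <- which.min(others$p)
      best_snp <- others$id[k]
      best_p <- others$p[k]
    }
  }
  list(study_span = st$span, ref_span = rf$span,
       fine_mapped = st$span < rf$span,
       refined = !is.na(best_p) && !is.na(index_p) && best_p < index_p,
       best_snp = best_snp, best_p = best_p, index_p = index_p)
}

#' Classify every index locus as exact / local / none / untested
#'
#' Orchestrates per-locus transferability: harmonizes alleles, applies the
#' exact rule at the index SNP, then — when not exact — tests every SNP of
#' the LD block containing the index with the spectral multiple-testing
#' correction. Index SNPs absent from the data are `untested`; exact takes
#' precedence over local, so no locus is ever both.
#'
#' @param catalog index-locus catalog (data.frame from
#'   [read_index_catalog()]).
#' @param assoc association results with `id`, `A1`, `A2`, `a1_freq`,
#'   `beta`, `p`, `pos`.
#' @param genotypes study [dosage_matrix()] (for block LD, r2 to index and
#'   n_eff).
#' @param blocks study block table from [gabriel_blocks()]; blocks are
#'   looked up by index position.
#' @param alpha significance level.
#' @param r2_min LD eligibility threshold for local calls.
#' @return data.frame, one row per catalog locus: `snp, status, index_p,
#'   consistent, best_snp, best_p, p_adj, n_eff, r2_to_index`.
#' @export
transfer_calls <- function(catalog, assoc, genotypes, blocks,
                           alpha = 0.05, r2_min = 0.3) {
  G <- hard_call(genotypes)$dosages
  rows <- vector("list", nrow(catalog))
  for (k in seq_len(nrow(catalog))) {
    loc <- catalog[k, ]
    row <- data.frame(snp = loc$SNP, status = "untested",
                      index_p = NA_real_, consistent = NA,
                      best_snp = NA_character_, best_p = NA_real_,
                      p_adj = NA_real_, n_eff = NA_real_,
                      r2_to_index = NA_real_, stringsAsFactors = FALSE)
    a <- assoc[match(loc$SNP, assoc$id), ]
    if (is.na(a$id[1]) || is.na(a$p)) {
      rows[[k]] <- row
      next
    }
    harm <- tryCatch(
      harmonize_alleles(loc$RISK_ALLELE, a$A1, a$A2, fold_maf(a$a1_freq)),
      error = function(e) list(multiplier = NA_real_, ambiguous = TRUE))
    ex <- classify_exact(a$p, a$beta, harm$multiplier, loc$REPORTED_OR, alpha)
    row$index_p <- a$p
    row$consistent <- ex$consistent
    if (is.na(harm$multiplier)) {
      row$status <- "untested"
      rows[[k]] <- row
      next
    }
    if (ex$exact) {
      row$status <- "exact"
      rows[[k]] <- row
      next
    }
    # local route over the block containing the index SNP
    hit <- if (is.null(blocks) || nrow(blocks) == 0) integer(0) else
      which(blocks$start_bp <= a$pos & blocks$end_bp >= a$pos)
    if (length(hit) == 0) {
      row$status <- "none"
      rows[[k]] <- row
      next
    }
    members <- strsplit(blocks$members[hit[1]], ",", fixed = TRUE)[[1]]
    block_assoc <- assoc[assoc$id %in% members, , drop = FALSE]
    gi <- G[, match(loc$SNP, colnames(G))]
    r2_to_index <- vapply(block_assoc$id, function(id) {
      gj <- G[, match(id, colnames(G))]
      if (stats::var(gj, na.rm = TRUE) == 0 ||
          stats::var(gi, na.rm = TRUE) == 0) return(NA_real_)
      suppressWarnings(stats::cor(gi, gj, use = "pairwise.complete.obs"))^2
    }, numeric(1))
    poly <- apply(G[, match(block_assoc$id, colnames(G)), drop = FALSE], 2,
                  function(x) stats::var(x, na.rm = TRUE) > 0)
    ne <- if (sum(poly) >= 1)
      effective_tests(G[, match(block_assoc$id[poly], colnames(G)),
                        drop = FALSE]) else 1
    lc <- classify_local(block_assoc, ne, loc$SNP, a$pos, r2_to_index,
                         alpha = alpha, r2_min = r2_min,
                         already_exact = FALSE)
    row$status <- lc$status
    row$best_snp <- lc$best_snp
    row$best_p <- lc$best_p
    row$p_adj <- lc$p_adj
    row$n_eff <- lc$n_eff
    row$r2_to_index <- lc$r2_to_index
    rows[[k]] <- row
  }
  do.call(rbind, rows)
}
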
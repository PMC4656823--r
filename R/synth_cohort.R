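#' Simulate a haplotype reference panel with block-structured LD
#'
#' Generates a binary haplotype panel organised into LD blocks. Within a
#' block, haplotypes are produced by a copy-with-mutation scheme: each
#' haplotype carries one latent block-ancestry uniform `u`; at each site with
#' target allele frequency `p_j` the haplotype copies the ancestral allele
#' `1(u < p_j)` with probability `within_block_ld`, and otherwise redraws the
#' allele independently as Bernoulli(`p_j`). At `within_block_ld = 1` the
#' realised columns of a block are nested indicator sets, so every
#' polymorphic within-block pair has |D'| = 1; at 0 all sites are
#' independent. Variants in different blocks are always generated
#' independently (free recombination between blocks).
#'
#' @param n_blocks number of LD blocks.
#' @param snps_per_block variants per block.
#' @param n_haplotypes number of haplotypes in the panel (2 x reference N).
#' @param within_block_ld copy probability in `[0, 1]` controlling expected
#'   within-block |D'|.
#' @param maf_range length-2 numeric in `(0, 0.5]`: per-site allele-1
#'   frequencies are drawn uniformly from this interval.
#' @param seed integer seed; fixed seed gives a bit-identical panel.
#' @param chrom chromosome label.
#' @param panel_tag free-text ancestry tag (e.g. `"EUR-like"`, `"YRI-like"`).
#' @param base_pos bp position of the first variant.
#' @param within_spacing_bp bp between consecutive variants of a block.
#' @param block_gap_bp extra bp gap between the last variant of a block and
#'   the first of the next.
#' @param positions_bp optional explicit positions (strictly increasing,
#'   length `n_blocks * snps_per_block`) overriding the regular layout —
#'   useful to place two panels with different block structure on identical
#'   coordinates.
#' @return An object of class `haplotype_panel`: list with `chrom`,
#'   `positions`, `haplotypes` (n_haplotypes x M 0/1 matrix),
#'   `block_assignment`, `alleles` (A1/A2 letters), `freq` (design
#'   frequencies), `monomorphic` flag, `panel_tag`.
#' @export
simulate_panel <- function(n_blocks, snps_per_block, n_haplotypes,
                           within_block_ld, maf_range = c(0.05, 0.5),
                           seed = 1L, chrom = "1", panel_tag = "synthetic",
                           base_pos = 1e6, within_spacing_bp = 1000,
                           block_gap_bp = 50000, positions_bp = NULL) {
  check_that(n_blocks >= 1 && snps_per_block >= 1 && n_haplotypes >= 1,
             "all counts must be >= 1")
  check_that(within_block_ld >= 0 && within_block_ld <= 1,
             "within_block_ld must be in [0, 1]")
  check_that(length(maf_range) == 2 && maf_range[1] > 0 && maf_range[2] <= 0.5,
             "maf_range must lie within (0, 0.5]")
  check_that(maf_range[2] - maf_range[1] >= 1e-9 || maf_range[1] == maf_range[2],
             "maf_range must be non-degenerate")
  check_that(maf_range[2] >= maf_range[1], "maf_range must be increasing")
  if (maf_range[2] > maf_range[1] && maf_range[2] - maf_range[1] < 1e-9) {
    abort("degenerate maf_range: width below resolution")
  }

  set.seed(seed)
  m <- n_blocks * snps_per_block
  block <- rep(seq_len(n_blocks), each = snps_per_block)
  p <- stats::runif(m, maf_range[1], maf_range[2])

  H <- matrix(0L, n_haplotypes, m)
  for (b in seq_len(n_blocks)) {
    cols <- which(block == b)
    u <- stats::runif(n_haplotypes) # shared block ancestry per haplotype
    for (j in cols) {
      copy <- stats::runif(n_haplotypes) < within_block_ld
      indep <- stats::runif(n_haplotypes) < p[j]
      H[, j] <- as.integer(ifelse(copy, u < p[j], indep))
    }
  }

  if (is.null(positions_bp)) {
    within_offsets <- (seq_len(snps_per_block) - 1) * within_spacing_bp
    block_starts <- base_pos +
      (seq_len(n_blocks) - 1) * ((snps_per_block - 1) * within_spacing_bp + block_gap_bp)
    positions <- as.integer(rep(block_starts, each = snps_per_block) +
                              rep(within_offsets, n_blocks))
  } else {
    check_that(length(positions_bp) == m && all(diff(positions_bp) > 0),
               "positions_bp must be strictly increasing of length %d", m)
    positions <- as.integer(positions_bp)
  }

  bases <- c("A", "C", "G", "T")
  a2 <- sample(bases, m, replace = TRUE)
  a1 <- vapply(a2, function(b) sample(setdiff(bases, b), 1L), character(1))

  cnt <- colSums(H)
  structure(list(
    chrom = chrom,
    positions = positions,
    haplotypes = H,
    block_assignment = block,
    alleles = data.frame(A1 = a1, A2 = unname(a2), stringsAsFactors = FALSE),
    freq = p,
    within_block_ld = within_block_ld,
    monomorphic = cnt == 0L | cnt == n_haplotypes,
    panel_tag = panel_tag
  ), class = "haplotype_panel")
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf("<haplotype_panel> %s: %d haplotypes x %d variants, %d blocks\n",
              x$panel_tag, nrow(x$haplotypes), ncol(x$haplotypes),
              max(x$block_assignment)))
  invisible(x)
}

# Variant metadata data.frame for a panel.
panel_variants <- function(panel, prefix = "snp") {
  m <- ncol(panel$haplotypes)
  data.frame(
    id = sprintf("%s%05d", prefix, seq_len(m)),
    chrom = panel$chrom,
    pos = panel$positions,
    A1 = panel$alleles$A1,
    A2 = panel$alleles$A2,
    imputed = FALSE,
    imp_r2 = NA_real_,
    block = panel$block_assignment,
    stringsAsFactors = FALSE
  )
}

#' Draw diploid genotypes from a haplotype panel
#'
#' With `draw = "panel"` each sample is the sum of two haplotypes drawn
#' uniformly with replacement from the panel, so the per-variant expected
#' allele frequency equals the realised panel frequency. Note that
#' resampling a finite panel creates genuine relatedness between samples
#' that happen to draw the same panel haplotype — at large sample sizes
#' this is detectable by IBD estimation. With `draw = "generative"` every
#' haplotype is instead generated afresh from the panel's generative
#' parameters (design frequencies, block structure and `within_block_ld`),
#' emulating an effectively infinite panel: samples are then exactly
#' unrelated, with expected allele frequencies equal to the design
#' frequencies.
#'
#' @param panel a [simulate_panel()] result.
#' @param n_samples number of diploid samples.
#' @param seed integer seed.
#' @param draw `"panel"` (resample realised haplotypes) or `"generative"`
#'   (fresh haplotypes from the generating process).
#' @return A [dosage_matrix()] of true genotypes in `{0, 1, 2}`.
#' @export
simulate_genotypes <- function(panel, n_samples, seed = 1L,
                               draw = c("panel", "generative")) {
  check_that(inherits(panel, "haplotype_panel"), "panel must be a haplotype_panel")
  draw <- match.arg(draw)
  nh <- nrow(panel$haplotypes)
  m <- ncol(panel$haplotypes)
  check_that(nh >= 1 && m >= 1, "empty panel")
  check_that(n_samples >= 1, "n_samples must be >= 1")
  set.seed(seed)
  if (draw == "panel") {
    i1 <- sample.int(nh, n_samples, replace = TRUE)
    i2 <- sample.int(nh, n_samples, replace = TRUE)
    g <- panel$haplotypes[i1, , drop = FALSE] + panel$haplotypes[i2, , drop = FALSE]
    storage.mode(g) <- "numeric"
  } else {
    g <- matrix(0, n_samples, m)
    block <- panel$block_assignment
    p <- panel$freq
    lambda <- panel$within_block_ld
    sizes <- table(block)
    singles <- which(block %in% as.integer(names(sizes)[sizes == 1]))
    if (length(singles)) {
      # single-site blocks have no within-block LD: plain HWE draws in bulk
      g[, singles] <- stats::rbinom(n_samples * length(singles), 2,
                                    rep(p[singles], each = n_samples))
    }
    for (b in unique(block[!(seq_len(m) %in% singles)])) {
      cols <- which(block == b)
      for (hap in 1:2) {
        u <- stats::runif(n_samples)
        for (j in cols) {
          copy <- stats::runif(n_samples) < lambda
          indep <- stats::runif(n_samples) < p[j]
          g[, j] <- g[, j] + as.integer(ifelse(copy, u < p[j], indep))
        }
      }
    }
  }
  rownames(g) <- sprintf("S%05d", seq_len(n_samples))
  dosage_matrix(g, panel_variants(panel))
}

#' Pair panel haplotypes into pseudo-diploid reference genotypes
#'
#' Deterministically pairs haplotypes (1,2), (3,4), ... so a reference panel
#' can be pushed through the same genotype-based LD machinery as the study
#' sample.
#'
#' @param panel a [simulate_panel()] result (even number of haplotypes).
#' @return A [dosage_matrix()].
#' @export
panel_genotypes <- function(panel) {
  nh <- nrow(panel$haplotypes)
  check_that(nh %% 2 == 0, "panel must have an even number of haplotypes")
  odd <- seq(1L, nh, by = 2L)
  g <- panel$haplotypes[odd, , drop = FALSE] + panel$haplotypes[odd + 1L, , drop = FALSE]
  storage.mode(g) <- "numeric"
  rownames(g) <- sprintf("R%05d", seq_along(odd))
  dosage_matrix(g, panel_variants(panel))
}

#' Flaw specification for synthetic cohorts
#'
#' Counts of quality-control defects planted by [inject_flaws()]. All
#' categories are disjoint.
#'
#' @param n_duplicates duplicated samples to append (exact genotype copies).
#' @param n_sex_discordant samples whose reported sex is flipped relative to
#'   their X-heterozygosity proxy.
#' @param n_related related samples: each has a fraction `related_pihat` of
#'   its genotypes replaced by exact copies from a partner sample, giving an
#'   expected IBD PiHat of `related_pihat`.
#' @param related_pihat target PiHat for planted relatives.
#' @param n_missing_variants variants that receive missing calls.
#' @param missing_rate per-sample missing probability at a flagged variant.
#' @param n_hwe_violations variants whose genotype column is replaced by an
#'   extreme heterozygote-excess column (all heterozygous), which fails any
#'   sensible HWE exact test at cohort size.
#' @return list of class `flaw_spec`.
#' @export
flaw_spec <- function(n_duplicates = 0L, n_sex_discordant = 0L,
                      n_related = 0L, related_pihat = 0.5,
                      n_missing_variants = 0L, missing_rate = 0.10,
                      n_hwe_violations = 0L) {
  check_that(all(c(n_duplicates, n_sex_discordant, n_related,
                   n_missing_variants, n_hwe_violations) >= 0),
             "flaw counts must be non-negative")
  check_that(related_pihat > 0 && related_pihat <= 1,
             "related_pihat must be in (0, 1]")
  structure(list(n_duplicates = as.integer(n_duplicates),
                 n_sex_discordant = as.integer(n_sex_discordant),
                 n_related = as.integer(n_related),
                 related_pihat = related_pihat,
                 n_missing_variants = as.integer(n_missing_variants),
                 missing_rate = missing_rate,
                 n_hwe_violations = as.integer(n_hwe_violations)),
            class = "flaw_spec")
}

#' Cohort simulation configuration
#'
#' @param n_cases,n_controls ascertained case/control counts (> 0).
#' @param causal_loci `NULL` or data.frame with columns `variant` (index or
#'   id), `or` (per-allele odds ratio for the risk allele) and optionally
#'   `risk` (`"A1"` or `"A2"`, default `"A1"`).
#' @param covariate_effects named log-odds coefficients for `age` (per
#'   year), `sexF` (female vs male) and `bmi` (per kg/m^2).
#' @param intercept logistic intercept; controls the base disease rate and
#'   hence how hard case ascertainment is.
#' @param flaw_spec a [flaw_spec()].
#' @param imputation_r2 `NULL` (no noise) or per-variant/scalar target
#'   squared correlation between emitted dosage and true genotype.
#' @param seed master seed; stage seeds are derived from it by label
#'   hashing ([derive_seed()]).
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(n_cases = 1035L, n_controls = 740L,
                          causal_loci = NULL,
                          covariate_effects = c(age = 0.03, sexF = -0.10, bmi = 0.02),
                          intercept = -3.0,
                          flaw_spec = loctransfer::flaw_spec(),
                          imputation_r2 = NULL, seed = 1L) {
  check_that(n_cases > 0 && n_controls > 0, "n_cases and n_controls must be > 0")
  if (!is.null(causal_loci)) {
    check_that(is.data.frame(causal_loci) &&
                 all(c("variant", "or") %in% names(causal_loci)),
               "causal_loci needs columns variant, or")
    check_that(all(causal_loci$or > 0), "odds ratios must be > 0")
    if (is.null(causal_loci$risk)) causal_loci$risk <- "A1"
  }
  if (!is.null(imputation_r2)) {
    check_that(all(imputation_r2 > 0 & imputation_r2 <= 1),
               "imputation_r2 must be in (0, 1]")
  }
  structure(list(n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
                 causal_loci = causal_loci, covariate_effects = covariate_effects,
                 intercept = intercept, flaw_spec = flaw_spec,
                 imputation_r2 = imputation_r2, seed = as.integer(seed)),
            class = "cohort_config")
}

# Draw covariates (age, sex, BMI) and the X-heterozygosity proxy used by the
# sex-discordance check. Distributions loosely match a middle-aged
# case-control diabetes cohort: age ~ N(54, 10), 59% female, BMI ~ N(26.3, 4.5).
draw_covariates <- function(n) {
  sex <- ifelse(stats::runif(n) < 0.59, "F", "M")
  xhet <- ifelse(sex == "F",
                 stats::rnorm(n, 0.22, 0.03),
                 stats::rnorm(n, 0.02, 0.008))
  data.frame(
    age = round(clamp(stats::rnorm(n, 54, 10), 25, 90), 1),
    sex = sex,
    bmi = round(clamp(stats::rnorm(n, 26.3, 4.5), 15, 50), 1),
    xhet = round(clamp(xhet, 0, 1), 4),
    stringsAsFactors = FALSE
  )
}

# Linear predictor of the disease model for a genotype pool.
disease_linpred <- function(dm, cov, config) {
  eta <- rep(config$intercept, nrow(dm$dosages))
  if (!is.null(config$causal_loci)) {
    for (k in seq_len(nrow(config$causal_loci))) {
      v <- config$causal_loci$variant[k]
      j <- if (is.character(v)) match(v, dm$variants$id) else as.integer(v)
      check_that(!is.na(j) && j >= 1 && j <= ncol(dm$dosages),
                 "causal locus %s not found", as.character(v))
      d <- dm$dosages[, j]
      if (identical(config$causal_loci$risk[k], "A2")) d <- 2 - d
      eta <- eta + log(config$causal_loci$or[k]) * d
    }
  }
  ce <- config$covariate_effects
  eta + ce[["age"]] * cov$age + ce[["sexF"]] * (cov$sex == "F") +
    ce[["bmi"]] * cov$bmi
}

#' Assign case-control phenotypes to a genotype pool
#'
#' Case status is drawn from the logistic model
#' `logit P(case) = intercept + sum_j log(OR_j) * risk-dosage_j + covariates`;
#' samples are then ascertained in row order until exactly `n_cases` cases
#' and `n_controls` controls are retained. The genotype pool must therefore
#' be larger than `n_cases + n_controls` unless the intercept already places
#' the case fraction near the target; if either quota cannot be filled from
#' the pool an error advises changing the intercept or pool size.
#'
#' @param genotypes a [dosage_matrix()] pool (rows are candidate samples).
#' @param config a [cohort_config()].
#' @return list with `samples` (data.frame: id, status 1/0, age, sex, bmi,
#'   xhet) and `keep` (row indices of `genotypes` retained, cases first is
#'   NOT guaranteed; order follows the pool).
#' @export
simulate_phenotypes <- function(genotypes, config) {
  check_that(inherits(config, "cohort_config"), "config must be a cohort_config")
  n_pool <- nrow(genotypes$dosages)
  n_target <- config$n_cases + config$n_controls
  check_that(n_pool >= n_target,
             "genotype pool (%d) smaller than n_cases + n_controls (%d)",
             n_pool, n_target)
  set.seed(derive_seed(config$seed, "phenotypes"))
  cov <- draw_covariates(n_pool)
  prob <- stats::plogis(disease_linpred(genotypes, cov, config))
  status <- as.integer(stats::runif(n_pool) < prob)

  case_rows <- which(status == 1L)[seq_len(min(sum(status == 1L), config$n_cases))]
  ctrl_rows <- which(status == 0L)[seq_len(min(sum(status == 0L), config$n_controls))]
  if (length(case_rows) < config$n_cases || length(ctrl_rows) < config$n_controls) {
    abort(paste0("could not ascertain %d cases and %d controls from a pool of %d ",
                 "(got %d / %d); adjust the intercept or enlarge the pool"),
          config$n_cases, config$n_controls, n_pool,
          length(case_rows), length(ctrl_rows))
  }
  keep <- sort(c(case_rows, ctrl_rows))
  samples <- data.frame(
    id = sample_ids(genotypes)[keep],
    status = status[keep],
    cov[keep, , drop = FALSE],
    stringsAsFactors = FALSE
  )
  rownames(samples) <- NULL
  list(samples = samples, keep = keep)
}

#' Simulate a full ascertained case-control cohort
#'
#' Convenience wrapper: draws a genotype pool of `pool_factor` times the
#' target size from the panel, phenotypes it with [simulate_phenotypes()],
#' keeps the ascertained subset, then optionally applies imputation noise
#' and plants QC flaws.
#'
#' @param panel a [simulate_panel()] result.
#' @param config a [cohort_config()].
#' @param pool_factor pool oversampling factor (>= 1).
#' @param draw haplotype draw mode, see [simulate_genotypes()].
#' @return list with `genotypes` (a [dosage_matrix()]; dosages if
#'   `config$imputation_r2` set), `true_genotypes`, `samples`, `ledger`
#'   (planted-flaw truth table).
#' @export
simulate_cohort <- function(panel, config, pool_factor = 4,
                            draw = c("panel", "generative")) {
  n_target <- config$n_cases + config$n_controls
  pool <- simulate_genotypes(panel, ceiling(n_target * pool_factor),
                             seed = derive_seed(config$seed, "genotypes"),
                             draw = match.arg(draw))
  ph <- simulate_phenotypes(pool, config)
  g <- pool[ph$keep, ]
  rownames(g$dosages) <- sprintf("S%05d", seq_len(nrow(g$dosages)))
  ph$samples$id <- rownames(g$dosages)

  fl <- inject_flaws(g, ph$samples, config$flaw_spec,
                     seed = derive_seed(config$seed, "flaws"))
  g <- fl$genotypes
  samples <- fl$samples

  true_g <- g
  if (!is.null(config$imputation_r2)) {
    g <- apply_imputation_noise(g, config$imputation_r2,
                                seed = derive_seed(config$seed, "imputation"))
  }
  list(genotypes = g, true_genotypes = true_g, samples = samples,
       ledger = fl$ledger)
}

#' Attenuate true genotypes into noisy imputed dosages
#'
#' Linear attenuation model: for a variant with true genotype `g`, A1
#' frequency `p` and target imputation quality `r2`, the emitted dosage is
#' `d = 2p + r (g - 2p) + e` with `r = sqrt(r2)` and `e` zero-mean Gaussian
#' noise of variance `(1 - r2) Var(g)`, clipped to `[0, 2]`. The squared
#' correlation between `d` and `g` converges to `r2` (clipping biases
#' extreme frequencies slightly). `r2 = 1` returns the genotypes unchanged.
#'
#' @param genotypes a [dosage_matrix()] of true genotypes.
#' @param imputation_r2 scalar or per-variant vector in `(0, 1]`.
#' @param seed integer seed.
#' @return A [dosage_matrix()] with continuous dosages, `imputed = TRUE` and
#'   `imp_r2` recorded in the variant metadata.
#' @export
apply_imputation_noise <- function(genotypes, imputation_r2, seed = 1L) {
  m <- ncol(genotypes$dosages)
  r2 <- rep_len(imputation_r2, m)
  check_that(all(r2 > 0 & r2 <= 1), "imputation_r2 must be in (0, 1]")
  set.seed(seed)
  g <- genotypes$dosages
  d <- g
  for (j in seq_len(m)) {
    gj <- g[, j]
    ok <- !is.na(gj)
    vg <- stats::var(gj[ok])
    if (r2[j] < 1 && vg > 0) {
      mu <- mean(gj[ok])
      r <- sqrt(r2[j])
      e <- stats::rnorm(sum(ok), 0, sqrt((1 - r2[j]) * vg))
      d[ok, j] <- clamp(mu + r * (gj[ok] - mu) + e, 0, 2)
    }
  }
  v <- genotypes$variants
  v$imputed <- TRUE
  v$imp_r2 <- r2
  dosage_matrix(d, v)
}

#' Plant QC flaws into a cohort and return the truth ledger
#'
#' Duplicates are exact genotype copies appended under new sample ids.
#' Sex-discordant samples have their reported sex flipped while the
#' X-heterozygosity proxy keeps signalling the original sex. Related samples
#' have a fraction `related_pihat` of their variants overwritten by their
#' partner's genotypes (expected method-of-moments PiHat equals that
#' fraction). Flagged variants receive missing calls at `missing_rate`;
#' HWE-violation variants are replaced by an all-heterozygote column. All
#' categories are disjoint; the ledger records every planted flaw.
#'
#' @param genotypes a [dosage_matrix()] of hard genotypes.
#' @param samples sample table aligned with `genotypes` rows.
#' @param spec a [flaw_spec()].
#' @param seed integer seed.
#' @return list with modified `genotypes`, `samples` and a `ledger`
#'   data.frame (category, id, partner, detail).
#' @export
inject_flaws <- function(genotypes, samples, spec, seed = 1L) {
  check_that(inherits(spec, "flaw_spec"), "spec must be a flaw_spec")
  check_that(nrow(samples) == nrow(genotypes$dosages),
             "sample table does not cover genotype rows")
  n <- nrow(samples)
  need <- spec$n_duplicates + spec$n_sex_discordant + 2L * spec$n_related
  check_that(need <= n, "flaw counts (%d samples needed) exceed cohort size %d",
             need, n)
  ledger <- data.frame(category = character(), id = character(),
                       partner = character(), detail = character(),
                       stringsAsFactors = FALSE)
  if (need == 0 && spec$n_missing_variants == 0 && spec$n_hwe_violations == 0) {
    return(list(genotypes = genotypes, samples = samples, ledger = ledger))
  }
  set.seed(seed)
  ids <- sample_ids(genotypes)
  pool <- sample(seq_len(n), need) # disjoint assignment
  take <- function(k) {
    if (k == 0) return(integer(0)) # -integer(0) would select nothing
    out <- pool[seq_len(k)]
    pool <<- pool[-seq_len(k)]
    out
  }
  dup_src <- take(spec$n_duplicates)
  sex_rows <- take(spec$n_sex_discordant)
  rel_recip <- take(spec$n_related)
  rel_donor <- take(spec$n_related)

  G <- genotypes$dosages
  samp <- samples

  if (spec$n_sex_discordant > 0) {
    samp$sex[sex_rows] <- ifelse(samp$sex[sex_rows] == "F", "M", "F")
    ledger <- rbind(ledger, data.frame(
      category = "sex_discordant", id = samp$id[sex_rows], partner = NA_character_,
      detail = "reported sex flipped", stringsAsFactors = FALSE))
  }
  if (spec$n_related > 0) {
    m <- ncol(G)
    for (k in seq_len(spec$n_related)) {
      copy <- stats::runif(m) < spec$related_pihat
      G[rel_recip[k], copy] <- G[rel_donor[k], copy]
    }
    ledger <- rbind(ledger, data.frame(
      category = "related", id = samp$id[rel_recip], partner = samp$id[rel_donor],
      detail = sprintf("target PiHat %.3f", spec$related_pihat),
      stringsAsFactors = FALSE))
  }
  if (spec$n_duplicates > 0) {
    dup_ids <- paste0(ids[dup_src], "_dup")
    Gd <- G[dup_src, , drop = FALSE]
    rownames(Gd) <- dup_ids
    G <- rbind(G, Gd)
    extra <- samp[dup_src, , drop = FALSE]
    extra$id <- dup_ids
    samp <- rbind(samp, extra)
    rownames(samp) <- NULL
    ledger <- rbind(ledger, data.frame(
      category = "duplicate", id = dup_ids, partner = ids[dup_src],
      detail = "exact genotype copy", stringsAsFactors = FALSE))
  }
  variant_pool <- sample(seq_len(ncol(G)),
                         spec$n_missing_variants + spec$n_hwe_violations)
  if (spec$n_missing_variants > 0) {
    miss_vars <- variant_pool[seq_len(spec$n_missing_variants)]
    for (j in miss_vars) {
      G[stats::runif(nrow(G)) < spec$missing_rate, j] <- NA
    }
    ledger <- rbind(ledger, data.frame(
      category = "missing_variant", id = genotypes$variants$id[miss_vars],
      partner = NA_character_,
      detail = sprintf("missing rate %.3f", spec$missing_rate),
      stringsAsFactors = FALSE))
  }
  if (spec$n_hwe_violations > 0) {
    hwe_vars <- variant_pool[spec$n_missing_variants + seq_len(spec$n_hwe_violations)]
    G[, hwe_vars] <- 1 # universal heterozygosity: maximal HWE violation
    ledger <- rbind(ledger, data.frame(
      category = "hwe_violation", id = genotypes$variants$id[hwe_vars],
      partner = NA_character_, detail = "all-heterozygote column",
      stringsAsFactors = FALSE))
  }
  list(genotypes = dosage_matrix(G, genotypes$variants), samples = samp,
       ledger = ledger)
}
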
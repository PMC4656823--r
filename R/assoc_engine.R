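#' Greedy windowed LD pruning
#'
#' Slides a window of `window` variants by `step`; within each window, for
#' every pair with squared dosage correlation above `r2_max` the
#' later-position variant is removed. Output preserves input order.
#'
#' @param genotypes a [dosage_matrix()].
#' @param window window size in variants (>= 2).
#' @param step slide in variants.
#' @param r2_max maximum tolerated pairwise r-squared.
#' @return Character vector of retained variant ids.
#' @export
ld_prune <- function(genotypes, window = 50L, step = 5L, r2_max = 0.5) {
  check_that(window >= 2, "window must be >= 2")
  check_that(step >= 1, "step must be >= 1")
  m <- ncol(genotypes$dosages)
  keep <- rep(TRUE, m)
  start <- 1L
  repeat {
    end <- min(start + window - 1L, m)
    idx <- which(keep[start:end]) + start - 1L
    if (length(idx) >= 2) {
      X <- genotypes$dosages[, idx, drop = FALSE]
      mu2 <- colMeans(X^2, na.rm = TRUE)
      mu <- colMeans(X, na.rm = TRUE)
      ok <- is.finite(mu) & (mu2 - mu^2) > 1e-12
      if (sum(ok) >= 2) {
        sub <- idx[ok]
        r2 <- fast_cor(X[, ok, drop = FALSE])^2
        for (a in seq_along(sub)[-length(sub)]) {
          if (!keep[sub[a]]) next
          later <- (a + 1):length(sub)
          hit <- later[keep[sub[later]] & !is.na(r2[a, later]) &
                         r2[a, later] > r2_max]
          if (length(hit)) keep[sub[hit]] <- FALSE
        }
      }
    }
    if (end >= m) break
    start <- start + step
  }
  variant_ids(genotypes)[keep]
}

# Column correlation matrix: BLAS crossprod when complete, pairwise
# complete observations otherwise.
fast_cor <- function(X) {
  if (anyNA(X)) {
    return(suppressWarnings(stats::cor(X, use = "pairwise.complete.obs")))
  }
  Xc <- sweep(X, 2, colMeans(X))
  s <- sqrt(colSums(Xc^2))
  s[s == 0] <- NA
  crossprod(Xc) / outer(s, s)
}

#' Principal components of standardized genotypes
#'
#' Dosage columns are centred at twice the allele frequency and scaled by
#' `sqrt(2 p (1 - p))` (the variance of a binomial(2, p) genotype); missing
#' dosages are mean-imputed (zero after centring). Returns the top-k sample
#' projections from the SVD of the standardized matrix.
#'
#' @param genotypes a [dosage_matrix()].
#' @param pruned_ids optional LD-pruned variant subset to use.
#' @param k number of components.
#' @return list with `scores` (n x k matrix), `eigenvalues` (length k,
#'   non-increasing; eigenvalues of the n x n sample covariance of
#'   standardized genotypes, i.e. `d^2 / m`).
#' @export
genotype_pca <- function(genotypes, pruned_ids = NULL, k = 3L) {
  dm <- if (is.null(pruned_ids)) genotypes else genotypes[, pruned_ids]
  X <- dm$dosages
  n <- nrow(X)
  m <- ncol(X)
  check_that(k <= min(n, m), "k exceeds min(samples, variants)")
  p <- colMeans(X, na.rm = TRUE) / 2
  sdv <- sqrt(2 * p * (1 - p))
  poly <- sdv > 0
  X <- X[, poly, drop = FALSE]
  Z <- sweep(X, 2, 2 * p[poly])
  Z <- sweep(Z, 2, sdv[poly], "/")
  Z[is.na(Z)] <- 0
  sv <- svd(Z, nu = k, nv = 0)
  check_that(k <= sum(sv$d > 1e-12 * sv$d[1]), "k exceeds matrix rank")
  scores <- sv$u %*% diag(sv$d[seq_len(k)], k, k)
  colnames(scores) <- paste0("PC", seq_len(k))
  rownames(scores) <- rownames(X)
  list(scores = scores, eigenvalues = sv$d[seq_len(k)]^2 / ncol(Z))
}

# Core IRLS logistic fit. X includes the intercept column.
# Returns beta, se, convergence/separation codes.
irls_logistic <- function(X, y, tol = 1e-8, max_iter = 50L) {
  beta <- rep(0, ncol(X))
  code <- "ok"
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    if (all(w < 1e-12)) {
      code <- "degenerate"
      break
    }
    XtW <- t(X * w)
    H <- XtW %*% X
    score <- drop(t(X) %*% (y - mu))
    delta <- tryCatch(solve(H, score), error = function(e) NULL)
    if (is.null(delta) || any(!is.finite(delta))) {
      code <- "degenerate"
      break
    }
    beta <- beta + delta
    if (max(abs(delta)) < tol) {
      attr(beta, "iterations") <- it
      break
    }
    if (it == max_iter) code <- "nonconverged"
  }
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  w <- mu * (1 - mu)
  H <- t(X * w) %*% X
  cov <- tryCatch(solve(H), error = function(e) NULL)
  if (is.null(cov) || any(!is.finite(diag(cov))) || any(diag(cov) <= 0)) {
    code <- "degenerate"
    se <- rep(NA_real_, ncol(X))
  } else {
    se <- sqrt(diag(cov))
  }
  if (code == "ok" && max(abs(beta)) > 15) code <- "separation"
  list(beta = beta, se = se, code = code)
}

#' Logistic regression of case status on an allelic dosage
#'
#' Maximum-likelihood logistic fit by iteratively reweighted least squares
#' (Newton scoring), convergence when the largest coefficient update falls
#' below `1e-8` or after 50 iterations. The per-variant result reports the
#' dosage term's log-odds coefficient, its standard error, and the
#' two-sided Wald p-value `2 * pnorm(-|beta/se|)`. Non-convergence,
#' separation or a degenerate (e.g. constant-dosage) fit is flagged in the
#' `code` field rather than raising an error.
#'
#' @param dosage numeric dosage vector (NAs dropped with their samples).
#' @param covariates `NULL`, or numeric matrix/data.frame of covariates.
#' @param status binary 0/1 vector.
#' @param id,a1,a2 variant annotation carried into the result.
#' @return One-row data.frame: `id, A1, A2, a1_freq, beta, se, p, n_used,
#'   code`.
#' @export
logistic_dosage_fit <- function(dosage, covariates = NULL, status,
                                id = "variant", a1 = "A1", a2 = "A2") {
  check_that(all(status %in% c(0, 1)), "status must be binary 0/1")
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    check_that(nrow(covariates) == length(dosage),
               "covariate rows != dosage length")
  }
  ok <- !is.na(dosage) & !is.na(status)
  if (!is.null(covariates)) ok <- ok & !rowAnyNA(covariates)
  d <- dosage[ok]
  y <- status[ok]
  n_used <- sum(ok)
  res <- data.frame(id = id, A1 = a1, A2 = a2,
                    a1_freq = mean(d) / 2,
                    beta = NA_real_, se = NA_real_, p = NA_real_,
                    n_used = n_used, code = "degenerate",
                    stringsAsFactors = FALSE)
  if (n_used < 2 || stats::var(d) == 0 || length(unique(y)) < 2) {
    return(res)
  }
  X <- cbind(`(Intercept)` = 1, dosage = d,
             if (!is.null(covariates)) covariates[ok, , drop = FALSE])
  fit <- irls_logistic(X, y)
  res$beta <- fit$beta[2]
  res$se <- fit$se[2]
  res$p <- if (is.na(fit$se[2])) NA_real_ else
    2 * stats::pnorm(-abs(fit$beta[2] / fit$se[2]))
  res$code <- fit$code
  res
}

rowAnyNA <- function(x) rowSums(is.na(x)) > 0

#' Dosage association scan over all variants
#'
#' Fits [logistic_dosage_fit()] per variant with the shared covariates
#' (age, sex as female indicator, BMI) and the leading genotype PCs.
#'
#' @param genotypes a [dosage_matrix()].
#' @param samples sample table with `id`, `status`, `age`, `sex`, `bmi`.
#' @param pcs `NULL` or an n x k PC score matrix aligned with samples.
#' @param covariate_cols which sample-table covariates to include.
#' @return data.frame of per-variant association results plus attribute
#'   `lambda_gc` (genomic inflation over the scan).
#' @export
assoc_scan <- function(genotypes, samples, pcs = NULL,
                       covariate_cols = c("age", "sex", "bmi")) {
  samples <- samples[match(sample_ids(genotypes), samples$id), ]
  cov <- NULL
  if (length(covariate_cols)) {
    cov <- samples[, covariate_cols, drop = FALSE]
    if ("sex" %in% names(cov)) cov$sex <- as.numeric(cov$sex == "F")
    cov <- as.matrix(cov)
  }
  if (!is.null(pcs)) cov <- cbind(cov, pcs)
  v <- genotypes$variants
  rows <- vector("list", nrow(v))
  for (j in seq_len(nrow(v))) {
    rows[[j]] <- logistic_dosage_fit(genotypes$dosages[, j], cov,
                                     samples$status,
                                     id = v$id[j], a1 = v$A1[j], a2 = v$A2[j])
  }
  out <- do.call(rbind, rows)
  out$chrom <- v$chrom
  out$pos <- v$pos
  chisq <- (out$beta / out$se)^2
  attr(out, "lambda_gc") <- if (sum(!is.na(chisq)) >= 2)
    genomic_inflation(chisq[!is.na(chisq)], warn = FALSE) else NA_real_
  out
}

#' Genomic inflation factor (lambda_GC)
#'
#' `lambda = median(chisq) / 0.455936`, the median of a 1-df chi-squared
#' variable. Values near 1 indicate well-controlled stratification.
#'
#' @param chisq vector of 1-df association chi-squared statistics.
#' @param warn warn when fewer than 100 statistics are supplied.
#' @return lambda (positive scalar).
#' @export
genomic_inflation <- function(chisq, warn = TRUE) {
  check_that(length(chisq) >= 1 && all(chisq >= 0, na.rm = TRUE),
             "chisq must be non-negative")
  if (warn && length(chisq) < 100) {
    warning("genomic_inflation: fewer than 100 statistics; estimate is noisy")
  }
  stats::median(chisq, na.rm = TRUE) / 0.455936
}
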
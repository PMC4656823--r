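#' Samples-by-variants allelic dosage matrix
#'
#' The central genotype container of the package: a numeric matrix of
#' A1-allele dosages in `[0, 2]` (rows = samples, columns = variants, `NA` =
#' missing) together with per-variant metadata. True genotypes are the
#' special case of integer dosages in `{0, 1, 2}`; imputed dosages are
#' continuous and carry an imputation quality r-squared.
#'
#' @param dosages numeric matrix, samples x variants, values in `[0, 2]` or
#'   `NA`. Row names are sample ids, column names variant ids (supplied via
#'   `variants$id` if absent).
#' @param variants data.frame with columns `id`, `chrom`, `pos`, `A1`, `A2`,
#'   and optionally `imputed` (logical) and `imp_r2` (numeric, `NA` for
#'   genotyped variants).
#' @return An object of class `dosage_matrix`.
#' @export
dosage_matrix <- function(dosages, variants) {
  check_that(is.matrix(dosages) && is.numeric(dosages),
             "dosages must be a numeric matrix")
  check_that(is.data.frame(variants), "variants must be a data.frame")
  required <- c("id", "chrom", "pos", "A1", "A2")
  missing_cols <- setdiff(required, names(variants))
  check_that(length(missing_cols) == 0,
             "variants is missing columns: %s", paste(missing_cols, collapse = ", "))
  check_that(nrow(variants) == ncol(dosages),
             "variants rows (%d) != dosage columns (%d)",
             nrow(variants), ncol(dosages))
  check_that(!anyDuplicated(variants$id), "duplicate variant ids")
  rng <- range(dosages, na.rm = TRUE)
  if (is.finite(rng[1])) {
    check_that(rng[1] >= -1e-9 && rng[2] <= 2 + 1e-9,
               "dosages outside [0, 2]: range %g..%g", rng[1], rng[2])
  }
  if (is.null(variants$imputed)) variants$imputed <- FALSE
  if (is.null(variants$imp_r2)) variants$imp_r2 <- NA_real_
  colnames(dosages) <- variants$id
  if (is.null(rownames(dosages))) {
    rownames(dosages) <- sprintf("S%05d", seq_len(nrow(dosages)))
  }
  structure(list(dosages = dosages, variants = variants),
            class = "dosage_matrix")
}

#' @export
print.dosage_matrix <- function(x, ...) {
  cat(sprintf("<dosage_matrix> %d samples x %d variants (%d imputed)\n",
              nrow(x$dosages), ncol(x$dosages), sum(x$variants$imputed)))
  invisible(x)
}

#' @export
dim.dosage_matrix <- function(x) dim(x$dosages)

#' Subset a dosage matrix by samples and/or variants
#'
#' @param x a [dosage_matrix()].
#' @param i sample selector (indices, logical, or sample ids).
#' @param j variant selector (indices, logical, or variant ids).
#' @param ... unused.
#' @return A `dosage_matrix`.
#' @export
`[.dosage_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$dosages))
  if (missing(j)) j <- seq_len(ncol(x$dosages))
  if (is.character(j)) j <- match(j, x$variants$id)
  d <- x$dosages[i, j, drop = FALSE]
  v <- x$variants[if (is.character(j)) match(colnames(d), x$variants$id) else j, ,
                  drop = FALSE]
  dosage_matrix(d, v)
}

#' Sample and variant ids
#' @param x a [dosage_matrix()].
#' @return character vector of ids.
#' @export
sample_ids <- function(x) rownames(x$dosages)

#' @rdname sample_ids
#' @export
variant_ids <- function(x) x$variants$id

#' Round dosages to hard genotype calls in \{0, 1, 2\}
#'
#' @param x a [dosage_matrix()].
#' @return A `dosage_matrix` whose values are integer genotypes (`NA`
#'   preserved).
#' @export
hard_call <- function(x) {
  g <- round(x$dosages)
  g[g < 0] <- 0
  g[g > 2] <- 2
  dosage_matrix(g, x$variants)
}

#' Per-variant A1 allele frequency (dosage mean / 2)
#' @param x a [dosage_matrix()].
#' @return numeric vector, one frequency per variant.
#' @export
a1_freq <- function(x) colMeans(x$dosages, na.rm = TRUE) / 2

#' Per-variant missingness and per-sample call rate
#' @param x a [dosage_matrix()].
#' @return numeric vector.
#' @export
variant_missingness <- function(x) colMeans(is.na(x$dosages))

#' @rdname variant_missingness
#' @export
sample_call_rate <- function(x) 1 - rowMeans(is.na(x$dosages))
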
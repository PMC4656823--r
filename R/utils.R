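#' Derive a stage-specific seed from a master seed
#'
#' All stochastic stages of the package draw their RNG state from a single
#' master seed combined with a stage label, so that a pipeline run is
#' reproducible end to end while stages remain decoupled (inserting a new
#' stage does not shift the streams of the others).
#'
#' The label is hashed with a 31-ary polynomial rolling hash modulo
#' 2^31 - 1 and mixed with the master seed by a Lehmer-style multiplier.
#' Everything stays below 2^31 so the result is a valid R integer seed.
#'
#' @param master integer master seed.
#' @param stage character stage label, e.g. `"phenotypes"`.
#' @return A single integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, stage) {
  stopifnot(length(master) == 1L, is.finite(master), length(stage) == 1L)
  m <- 2147483647 # 2^31 - 1, prime
  h <- 0
  for (ch in utf8ToInt(as.character(stage))) {
    h <- (h * 31 + ch) %% m
  }
  # 48271 is the MINSTD multiplier; products stay < 2^53 so doubles are exact
  s <- (abs(as.numeric(master)) %% m) + 1
  mixed <- (s * 48271 + h * 16807) %% m
  as.integer(mixed %% (m - 2)) + 1L
}

#' DNA complement of allele codes
#' @param x character vector of single-base alleles (A/C/G/T).
#' @return complementary alleles.
#' @keywords internal
complement_allele <- function(x) chartr("ACGT", "TGCA", toupper(x))

# Clamp numeric vector into [lo, hi].
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Fold an allele frequency to the minor side.
fold_maf <- function(f) pmin(f, 1 - f)

# stop() with call. = FALSE and sprintf-style formatting
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Internal check helper
check_that <- function(ok, fmt, ...) if (!isTRUE(ok)) abort(fmt, ...)
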
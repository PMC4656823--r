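#' Power specification for allelic replication tests
#'
#' @param or per-allele odds ratio to detect (> 0).
#' @param raf risk-allele frequency in controls, in (0, 1).
#' @param n_cases,n_controls sample sizes.
#' @param alpha one-sided significance level in (0, 0.5); one-sided because
#'   replication requires the same direction of effect.
#' @return list of class `power_spec`.
#' @export
power_spec <- function(or, raf, n_cases = 1035L, n_controls = 740L,
                       alpha = 0.05) {
  check_that(or > 0, "OR must be > 0")
  check_that(raf > 0 && raf < 1, "raf must be in (0, 1)")
  check_that(n_cases > 0 && n_controls > 0, "sample sizes must be > 0")
  check_that(alpha > 0 && alpha < 0.5, "alpha must be in (0, 0.5)")
  structure(list(or = or, raf = raf, n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls), alpha = alpha),
            class = "power_spec")
}

#' Analytic power for replicating a per-allele odds ratio
#'
#' Allelic (per-chromosome) Wald test on the log odds ratio. With control
#' risk-allele frequency `p0`, the case frequency under the alternative is
#' `p1 = p0 OR / (1 + p0 (OR - 1))`; the log-OR variance is
#' `1/(2 n1 p1) + 1/(2 n1 (1-p1)) + 1/(2 n0 p0) + 1/(2 n0 (1-p0))`, and
#' power at one-sided level alpha is
#' `Phi(log(OR)/sqrt(var) - z_{1-alpha})`. At OR = 1 this reduces to alpha
#' exactly.
#'
#' @param spec a [power_spec()].
#' @return Power in `[0, 1]`.
#' @export
power_analytic <- function(spec) {
  check_that(inherits(spec, "power_spec"), "spec must be a power_spec")
  p0 <- spec$raf
  p1 <- p0 * spec$or / (1 + p0 * (spec$or - 1))
  v <- 1 / (2 * spec$n_cases * p1) + 1 / (2 * spec$n_cases * (1 - p1)) +
    1 / (2 * spec$n_controls * p0) + 1 / (2 * spec$n_controls * (1 - p0))
  stats::pnorm(log(spec$or) / sqrt(v) - stats::qnorm(1 - spec$alpha))
}

#' Simulation-based power (validation oracle for the analytic formula)
#'
#' Simulates 2x2 allele-count tables under the alternative, applies the
#' one-sided Wald test on the log odds ratio (0.5 continuity correction
#' when any cell is empty) and reports the rejection fraction with its
#' binomial Monte-Carlo standard error.
#'
#' @param spec a [power_spec()].
#' @param n_reps number of replicates (>= 100).
#' @param seed integer seed.
#' @return list: `power`, `mc_se`, `n_reps`.
#' @export
power_simulated <- function(spec, n_reps = 2000L, seed = 1L) {
  check_that(inherits(spec, "power_spec"), "spec must be a power_spec")
  check_that(n_reps >= 100, "n_reps must be >= 100")
  set.seed(seed)
  p0 <- spec$raf
  p1 <- p0 * spec$or / (1 + p0 * (spec$or - 1))
  m1 <- 2 * spec$n_cases
  m0 <- 2 * spec$n_controls
  a <- stats::rbinom(n_reps, m1, p1) # risk alleles in cases
  c_ <- stats::rbinom(n_reps, m0, p0)
  b <- m1 - a
  d <- m0 - c_
  cc <- (a == 0 | b == 0 | c_ == 0 | d == 0) * 0.5
  lor <- log((a + cc) * (d + cc) / ((b + cc) * (c_ + cc)))
  se <- sqrt(1 / (a + cc) + 1 / (b + cc) + 1 / (c_ + cc) + 1 / (d + cc))
  z <- lor / se
  rej <- mean(z > stats::qnorm(1 - spec$alpha))
  list(power = rej, mc_se = sqrt(rej * (1 - rej) / n_reps), n_reps = n_reps)
}

#' Analytic power over an OR x RAF grid
#'
#' @param or_values vector of odds ratios.
#' @param raf_values vector of control risk-allele frequencies.
#' @param n_cases,n_controls sample sizes.
#' @param alpha one-sided level.
#' @return data.frame with columns `or`, `raf`, `power` (Cartesian grid).
#' @export
power_grid <- function(or_values, raf_values, n_cases = 1035L,
                       n_controls = 740L, alpha = 0.05) {
  check_that(length(or_values) >= 1 && length(raf_values) >= 1,
             "grids must be non-empty")
  g <- expand.grid(or = or_values, raf = raf_values,
                   KEEP.OUT.ATTRS = FALSE)
  g$power <- mapply(function(o, f) {
    power_analytic(power_spec(o, f, n_cases, n_controls, alpha))
  }, g$or, g$raf)
  g
}
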
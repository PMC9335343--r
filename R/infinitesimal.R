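#' Kimura fixation probability for a haploid Wright-Fisher population
#'
#' Diffusion-approximation probability that an allele at frequency `p` with
#' selection coefficient `s` ultimately fixes in a haploid population of size
#' `N`:
#' \deqn{u(p) = \frac{1 - e^{-2 N s p}}{1 - e^{-2 N s}},}
#' with the continuous neutral limit \eqn{u(p) = p} at \eqn{s = 0}. `u(p)` is
#' increasing in both `p` and `s`, and exceeds `p` exactly when `s > 0`.
#'
#' @param p Initial frequency (vectorized, in `[0, 1]`).
#' @param N Haploid population size.
#' @param s Per-generation selection coefficient (vectorized).
#' @return Fixation probabilities, same length as `p`/`s` recycled.
#' @export
#' @examples
#' fixation_probability(0.1, N = 20, s = 0.05)
#' fixation_probability(0.3, N = 100, s = 0)  # neutral: u = p
fixation_probability <- function(p, N, s) {
  if (any(p < 0 | p > 1)) stop_invalid("`p` must lie in [0, 1]")
  check_number(N, "N", lower = 1)
  out <- numeric(length(pmax(p, s)))
  p <- rep_len(p, length(out))
  s <- rep_len(s, length(out))
  x <- 2 * N * s
  nearly_neutral <- abs(x) < 1e-8
  out[nearly_neutral] <- p[nearly_neutral]
  i <- !nearly_neutral
  # expm1 keeps the ratio stable for small and large |2Ns|
  out[i] <- expm1(-x[i] * p[i]) / expm1(-x[i])
  out
}

#' Robertson's limit to the total selection response
#'
#' Under the infinitesimal model the genetic variance erodes only by
#' inbreeding, so it persists for about \eqn{2 N_e} generations and the total
#' change in the trait mean is bounded by \eqn{2 N_e R_1}, where \eqn{R_1} is
#' the change in the first generation. `Ne` here is the inbreeding-effective
#' size in the diploid-standard parameterization: a haploid Wright-Fisher
#' population of census size `n` loses heterozygosity at rate `1/n` per
#' generation and so corresponds to `Ne = n/2`.
#'
#' @param Ne Effective population size (`>= 1`).
#' @param R1 First-generation selection response (trait units per generation).
#' @return The limiting total response, `2 * Ne * R1` (trait units).
#' @export
#' @examples
#' robertson_total_response(Ne = 100, R1 = 0.05)  # 10
robertson_total_response <- function(Ne, R1) {
  check_number(Ne, "Ne", lower = 1)
  2 * Ne * R1
}

#' Ultimate response as a sum of fixation-probability biases
#'
#' The ultimate change in the trait mean under directional selection is the
#' sum over loci of the effect size times the difference between the allele's
#' fixation probability and its initial frequency:
#' \deqn{\Delta Z_\infty = \sum_i \gamma_i \left[u(p_{0i}; n, s_i) -
#'   p_{0i}\right], \qquad s_i = \beta \gamma_i.}
#' In the weak-selection (infinitesimal) limit \eqn{n s_i \ll 1} this
#' recovers Robertson's limit: \eqn{u(p) - p \to n s p q}, so
#' \eqn{\Delta Z_\infty \to n \beta \sum_i \gamma_i^2 p_{0i} q_{0i}
#'   = 2 N_e R_1} with \eqn{N_e = n/2}.
#'
#' @param arch A [genetic_architecture] (or data frame with a `gamma` column).
#' @param n Haploid population size.
#' @param beta Directional selection gradient on the trait.
#' @param p0 Initial frequency, a scalar or per-locus vector.
#' @return The ultimate change in trait mean (trait units).
#' @export
#' @examples
#' arch <- sample_architecture(50, mean_effect = 0.01, seed = 1)
#' ultimate_response_bias_sum(arch, n = 100, beta = 0.05, p0 = 0.5)
ultimate_response_bias_sum <- function(arch, n, beta, p0 = 0.5) {
  gamma <- arch$gamma
  p0 <- rep_len(p0, length(gamma))
  u <- fixation_probability(p0, N = n, s = beta * gamma)
  sum(gamma * (u - p0))
}

#' Expected favorable substitutions across genetic architectures
#'
#' Scans architectures of `L` equally selected loci while holding the total
#' variance in relative fitness \eqn{\sum_i s_i^2 p_0 q_0} fixed (the
#' reproductive capacity of the organism bounds how much selection it can
#' sustain). For each `L` the per-locus coefficient is
#' \eqn{s = \sqrt{V_w / (L\, p_0 q_0)}} and the expected number of favorable
#' substitutions is \eqn{L\, u(p_0; n, s)}. As `L` grows, per-locus selection
#' weakens into the drift-dominated regime (\eqn{N_e s < 1}), yet the
#' expected *excess* of substitutions over the neutral expectation
#' \eqn{L p_0} keeps increasing: adaptation is most efficient in the
#' infinitesimal limit.
#'
#' @param L_grid Integer vector of architecture sizes to scan.
#' @param fitness_variance Total variance in relative fitness held fixed
#'   across the scan (dimensionless, `> 0`).
#' @param n Haploid population size.
#' @param p0 Initial frequency of each favored allele (default 0.5).
#' @return A tibble `(L, s, Ns, expected_substitutions,
#'   excess_substitutions)` of class `efficiency_scan`.
#' @export
#' @examples
#' efficiency_scan(c(1, 10, 100, 1000), fitness_variance = 0.01, n = 100)
efficiency_scan <- function(L_grid, fitness_variance, n, p0 = 0.5) {
  check_number(fitness_variance, "fitness_variance", lower = 0, strict_lower = TRUE)
  check_number(p0, "p0", lower = 0, upper = 1)
  if (any(L_grid < 1)) stop_invalid("`L_grid` must be >= 1")
  s <- sqrt(fitness_variance / (L_grid * p0 * (1 - p0)))
  u <- vapply(s, function(si) fixation_probability(p0, N = n, s = si), numeric(1))
  out <- tibble::tibble(
    L = as.integer(L_grid), s = s, Ns = n * s,
    expected_substitutions = L_grid * u,
    excess_substitutions = L_grid * (u - p0)
  )
  class(out) <- c("efficiency_scan", class(out))
  out
}

#' Simulated check of Robertson's limit in the infinitesimal regime
#'
#' Runs replicate directional-selection Wright-Fisher simulations (fitness
#' \eqn{\propto e^{\beta z}}) from standing variation at `p0 = 1/2`, with
#' per-locus scaled selection \eqn{n \beta \gamma} deep in the
#' drift-dominated regime, and compares the replicate-mean cumulative
#' response with \eqn{2 N_e R_1} (with \eqn{N_e = n/2} for a haploid census
#' of `n`). `R1` is the deterministic expected first-generation response
#' (the selection update applied to the initial frequencies, before drift);
#' the realized first-generation change equals it in expectation but carries
#' drift noise far larger than the signal at these sizes. Fixed loci are
#' absorbing (no mutation) and are dropped from the resampling as they fix.
#'
#' @param n Haploid population size (effective size `Ne = n/2`).
#' @param L Number of loci, each of effect `gamma`.
#' @param gamma Per-locus effect size.
#' @param beta Directional selection gradient; `n * beta * gamma` should be
#'   well below 1 for the infinitesimal regime (the default 0.09 is flagged
#'   otherwise).
#' @param replicates Number of replicate populations.
#' @param max_generations Cap on generations per replicate (loci still
#'   segregating at the cap contribute their current frequencies; the
#'   expected unrealized response decays like \eqn{e^{-2 t / n}}).
#' @param seed Optional master seed.
#' @return A list of class `robertson_fit`: `ratio` (total response over
#'   `Ne * R1`), `se_ratio`, `R1`, `mean_total`, `Ne`, and the per-replicate
#'   totals.
#' @export
robertson_experiment <- function(n = 200, L = 2000, gamma = 0.01,
                                 beta = 0.045, replicates = 200,
                                 max_generations = 20 * n, seed = NULL) {
  check_number(n, "n", lower = 2)
  check_number(L, "L", lower = 1)
  if (!is.null(seed)) set.seed(seed)
  if (n * beta * gamma >= 1) {
    warning("n * beta * gamma >= 1: not in the drift-dominated regime")
  }
  wr <- exp(beta * gamma)
  # deterministic expected first-generation response at p0 = 1/2
  dp1 <- 0.5 * wr / (0.5 * wr + 0.5) - 0.5
  R1 <- L * gamma * dp1
  totals <- vapply(seq_len(replicates), function(r) {
    p <- rep(0.5, L)
    for (t in seq_len(max_generations)) {
      seg <- p > 0 & p < 1
      if (!any(seg)) break
      ps <- p[seg] * wr
      ps <- ps / (ps + 1 - p[seg])
      p[seg] <- rbinom(sum(seg), n, ps) / n
    }
    sum(gamma * (p - 0.5))
  }, numeric(1))
  Ne <- n / 2
  structure(
    list(ratio = mean(totals) / (Ne * R1),
         se_ratio = sd(totals) / sqrt(replicates) / (Ne * R1),
         R1 = R1, mean_total = mean(totals), Ne = Ne, n = n, L = L,
         gamma = gamma, beta = beta, replicates = replicates,
         totals = totals),
    class = "robertson_fit"
  )
}

#' @export
print.robertson_fit <- function(x, ...) {
  cat("<robertson_fit>", x$replicates, "replicates, n =", x$n,
      "(Ne =", x$Ne, ")\n")
  cat("  total response / (Ne * R1) =", format(x$ratio, digits = 4),
      "+/-", format(x$se_ratio, digits = 2), "(expected 2)\n")
  invisible(x)
}
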
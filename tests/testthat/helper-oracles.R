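# Independent oracles used across tests. These deliberately avoid the
# package's own code paths.

# Exact fixation probability of a haploid Wright-Fisher chain with selection:
# states k = 0..N copies; deterministic selection p* = p(1+s)/(1+ps) followed
# by binomial resampling. Solves the absorption system directly.
wf_absorption_probability <- function(k0, N, s) {
  p <- (0:N) / N
  pstar <- p * (1 + s) / (1 + p * s)
  P <- t(vapply(pstar, function(ps) dbinom(0:N, N, ps), numeric(N + 1)))
  # u = P u with u(0)=0, u(N)=1; solve for interior states
  interior <- 2:N  # row/col indices of states 1..N-1
  A <- diag(N - 1) - P[interior, interior, drop = FALSE]
  b <- P[interior, N + 1]
  u <- solve(A, b)
  c(0, u, 1)[k0 + 1]
}

# Exact one-generation expected frequency change at a single biallelic locus
# under the centered trait convention: two genotype classes with trait values
# +gamma/2 and -gamma/2 and Gaussian stabilizing fitness.
single_locus_expected_change <- function(p, gamma, zopt, Vs) {
  w_plus <- exp(-(gamma / 2 - zopt)^2 / (2 * Vs))
  w_minus <- exp(-(-gamma / 2 - zopt)^2 / (2 * Vs))
  p * w_plus / (p * w_plus + (1 - p) * w_minus) - p
}

# a minimal wf_trajectory-like object for observable unit tests
fake_trajectory <- function(locus_paths, summary = NULL, n = 100) {
  structure(
    list(summary = summary, locus_paths = locus_paths,
         checkpoints = tibble::tibble(generation = integer(),
                                      locus = integer(), freq = numeric()),
         params = list(n = n)),
    class = "wf_trajectory"
  )
}
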
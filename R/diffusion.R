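#' Stationary allele-frequency density under mutation, drift, and
#' stabilizing selection
#'
#' Unnormalized stationary density of the per-locus allele frequency for a
#' locus of effect `gamma`, with the trait mean at the optimum. Assembled from
#' the engine's own forces by the standard stationary-density construction
#' (drift variance \eqn{pq/n}, symmetric mutation \eqn{\mu(1-2p)}, and the
#' at-optimum selection term \eqn{\Delta p = pq\,\gamma^2 (p - 1/2)/V_s}):
#' \deqn{\psi(p) \propto (pq)^{\theta - 1}
#'   \exp\left(-\frac{n \gamma^2 p q}{V_s}\right), \qquad \theta = 2 n \mu.}
#' The neutral limit \eqn{\gamma = 0} is the Beta(\eqn{\theta, \theta})
#' kernel; the density is symmetric in \eqn{p \leftrightarrow 1 - p}. At the
#' study conditions \eqn{\theta = 1/2}, so the endpoint singularities are
#' integrable but sharp, which is why the quadrature below substitutes
#' \eqn{p = \sin^2(\phi/2)}.
#'
#' @param p Frequencies at which to evaluate (in `(0, 1)`).
#' @param gamma Locus effect size (`>= 0`).
#' @param params A [sim_params] (uses `n`, `mu`, `Vs`).
#' @return Unnormalized density values at `p`.
#' @export
#' @examples
#' par <- sim_params()
#' p <- c(0.1, 0.5, 0.9)
#' stationary_density(p, gamma = 0.12, params = par)
stationary_density <- function(p, gamma, params) {
  check_number(gamma, "gamma", lower = 0)
  theta <- 2 * params$n * params$mu
  pq <- p * (1 - p)
  pq^(theta - 1) * exp(-params$n * gamma^2 * pq / params$Vs)
}

# E[pq] under the stationary density, via the sin^2(phi/2) substitution.
# method "adaptive" uses stats::integrate on the phi scale (smooth integrand);
# "grid" is an independent dense-trapezoid cross-check on the same scale.
epq_one <- function(gamma, theta, nVs, method = "adaptive", grid_n = 20000L) {
  # p = sin^2(phi/2): dp = sin(phi)/2 dphi, pq = sin^2(phi)/4, so
  # psi(p) dp = 4^(1-theta)/2 * sin(phi)^(2 theta - 1) exp(-c pq) dphi,
  # finite on (0, pi) for any theta > 0
  f <- function(phi, moment) {
    pq <- sin(phi)^2 / 4
    4^(1 - theta) / 2 * sin(phi)^(2 * theta - 1) *
      exp(-nVs * gamma^2 * pq) * pq^moment
  }
  if (method == "adaptive") {
    num <- integrate(f, 0, pi, moment = 1, rel.tol = 1e-10)
    den <- integrate(f, 0, pi, moment = 0, rel.tol = 1e-10)
    if (num$message != "OK" || den$message != "OK") {
      abort("stationary-density quadrature failed to converge",
            class = "polyadapt_numeric_failure")
    }
    num$value / den$value
  } else {
    # midpoint rule on an open grid avoids evaluating the endpoints
    phi <- (seq_len(grid_n) - 0.5) * pi / grid_n
    sum(f(phi, 1)) / sum(f(phi, 0))
  }
}

#' Expected heterozygosity and variance contribution of one locus
#'
#' Computes \eqn{E[pq] = \int pq\,\psi(p)\,dp / \int \psi(p)\,dp} under the
#' [stationary_density()] by quadrature that removes the endpoint
#' singularities with the substitution \eqn{p = \sin^2(\phi/2)}, and the
#' resulting per-locus contribution to the equilibrium genetic variance,
#' \eqn{\gamma^2 E[pq]}. In the neutral limit this reduces to the
#' Beta-moment closed form \eqn{E[pq] = \theta / (2 (2\theta + 1))}.
#'
#' @param gamma Vector of locus effect sizes (`>= 0`).
#' @param params A [sim_params].
#' @param method `"adaptive"` (default; adaptive quadrature on the
#'   substituted scale) or `"grid"` (dense trapezoid cross-check).
#' @return A tibble `(gamma, e_pq, var_contribution)`.
#' @export
#' @examples
#' expected_locus_variance(c(0, 0.12, 0.3), sim_params())
expected_locus_variance <- function(gamma, params, method = c("adaptive", "grid")) {
  method <- match.arg(method)
  if (any(gamma < 0)) stop_invalid("`gamma` must be >= 0")
  theta <- 2 * params$n * params$mu
  nVs <- params$n / params$Vs
  e_pq <- vapply(gamma, epq_one, numeric(1), theta = theta, nVs = nVs,
                 method = method)
  tibble::tibble(gamma = gamma, e_pq = e_pq,
                 var_contribution = gamma^2 * e_pq)
}

#' Diffusion-approximation prediction of the equilibrium genetic variance
#'
#' Predicts the equilibrium genetic variance maintained at
#' mutation-selection-drift balance by summing per-locus expected variance
#' contributions under the stationary density: for a concrete architecture,
#' \eqn{V_g^{pred} = \sum_i \gamma_i^2 E[pq \mid \gamma_i]}; for an
#' exponential effect-size distribution,
#' \eqn{V_g^{pred} = L \int \gamma^2 E[pq \mid \gamma] f(\gamma)\, d\gamma}.
#'
#' @param arch Either a [genetic_architecture] (or any data frame with a
#'   `gamma` column), or `NULL` to use the exponential effect-size
#'   distribution given by `L` and `mean_effect`.
#' @param params A [sim_params].
#' @param L,mean_effect Architecture-distribution parameters, used when
#'   `arch` is `NULL`.
#' @return A list of class `diffusion_prediction` with elements `theta`,
#'   `vg_pred`, and `per_effect_table` (a tibble `gamma`, `e_pq`,
#'   `var_contribution`; for the distribution version the table is evaluated
#'   on a grid of representative effects).
#' @export
#' @examples
#' pred <- predict_equilibrium_vg(params = sim_params(), L = 1000,
#'                                mean_effect = 0.12)
#' glance(pred)
predict_equilibrium_vg <- function(arch = NULL, params = sim_params(),
                                   L = 1000, mean_effect = 0.12) {
  theta <- 2 * params$n * params$mu
  if (!is.null(arch)) {
    tab <- expected_locus_variance(arch$gamma, params)
    vg <- sum(tab$var_contribution)
  } else {
    check_number(L, "L", lower = 1)
    check_number(mean_effect, "mean_effect", lower = 0, strict_lower = TRUE)
    nVs <- params$n / params$Vs
    integrand <- function(g) {
      vapply(g, function(gi) {
        gi^2 * epq_one(gi, theta, nVs) * dexp(gi, rate = 1 / mean_effect)
      }, numeric(1))
    }
    # effects beyond ~60 means carry negligible exponential weight
    vg <- L * integrate(integrand, 0, 60 * mean_effect, rel.tol = 1e-8)$value
    tab <- expected_locus_variance(mean_effect * c(0.25, 0.5, 1, 2, 4), params)
  }
  structure(list(theta = theta, vg_pred = vg, per_effect_table = tab,
                 params = params),
            class = "diffusion_prediction")
}

#' @export
print.diffusion_prediction <- function(x, ...) {
  cat("<diffusion_prediction> theta =", format(x$theta, digits = 4),
      " predicted equilibrium Vg =", format(x$vg_pred, digits = 4), "\n")
  invisible(x)
}
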
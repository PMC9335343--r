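#' Expected per-locus frequency change due to selection
#'
#' Mean-field selection update of the allele-frequency engine, assuming linkage
#' equilibrium and an (approximately) Gaussian distribution of background
#' breeding values. For Gaussian stabilizing selection with optimum
#' \eqn{z_{opt}} and width `Vs`, conditioning on the allele carried at locus
#' `i` shifts the trait mean to \eqn{\bar z + \gamma_i q_i} ("+" allele) or
#' \eqn{\bar z - \gamma_i p_i} ("-" allele). Integrating the Gaussian fitness
#' over the background gives the exact allelic fitness ratio
#' \deqn{\log(w_+/w_-) = \frac{\gamma_i(z_{opt} - \bar z) +
#'   \gamma_i^2 (p_i - 1/2)}{V_s + V_{-i}},}
#' where \eqn{V_{-i}} is the genetic variance excluding locus `i`
#' (`method = "gaussian"`, the default). Expanding to first order in
#' \eqn{1/V_s} gives the per-locus selection coefficient
#' \eqn{s_i = \gamma_i (z_{opt} - \bar z)/V_s + \gamma_i^2 (p_i - 1/2)/V_s}
#' and \eqn{\Delta p_i = p_i q_i s_i} (`method = "first_order"`; faster, and
#' the form used by the analytic theory). Under directional selection
#' (fitness \eqn{\propto e^{\beta z}}) the allelic fitness ratio is exactly
#' \eqn{e^{\beta\gamma_i}} and the background cancels.
#'
#' The first, directional term vanishes when the mean sits at the optimum; the
#' second term then selects against heterozygosity, pushing loci with
#' \eqn{p > 1/2} up and loci with \eqn{p < 1/2} down.
#'
#' @param state A frequency-engine [population_state][initial_state].
#' @param arch A [genetic_architecture].
#' @param zopt Current trait optimum (trait units).
#' @param Vs Width of stabilizing selection (`> 0`).
#' @param method `"gaussian"` or `"first_order"`; see Details.
#' @param selection `"stabilizing"` or `"directional"`.
#' @param beta Directional selection gradient (used when
#'   `selection = "directional"`).
#'
#' @return Numeric vector of expected per-locus frequency changes
#'   \eqn{\Delta p_i}; `p + selection_delta(...)` always lies in `[0, 1]`.
#' @export
#' @examples
#' arch <- sample_architecture(10, seed = 1)
#' st <- initial_state(arch, sim_params(), mode = "half")
#' # mean at optimum and p = 1/2: both terms vanish
#' max(abs(selection_delta(st, arch, zopt = 0, Vs = 20)))
selection_delta <- function(state, arch, zopt, Vs,
                            method = c("gaussian", "first_order"),
                            selection = c("stabilizing", "directional"),
                            beta = 0) {
  method <- match.arg(method)
  selection <- match.arg(selection)
  check_number(Vs, "Vs", lower = 0, strict_lower = TRUE)
  p <- state$p
  if (is.null(p)) stop_invalid("selection_delta() needs a frequency-engine state")
  gamma <- arch$gamma
  q <- 1 - p
  if (selection == "directional") {
    w <- exp(beta * gamma)
    return(p * w / (p * w + q) - p)
  }
  zbar <- trait_mean_internal(p, gamma, attr(arch, "centering"))
  if (method == "first_order") {
    s <- (gamma * (zopt - zbar) + gamma^2 * (p - 0.5)) / Vs
    delta <- p * q * s
    # the linearized update can overshoot the boundary; clip the landing point
    return(clamp01(p + delta) - p)
  }
  vc <- gamma^2 * p * q
  Vb <- Vs + pmax(sum(vc) - vc, 0)
  w <- exp((gamma * (zopt - zbar) + gamma^2 * (p - 0.5)) / Vb)
  p * w / (p * w + q) - p
}

# trait mean for a frequency vector under either centering convention
trait_mean_internal <- function(p, gamma, centering) {
  if (identical(centering, "raw")) sum(gamma * p) else sum(gamma * (p - 0.5))
}

#' Deterministic symmetric mutation update
#'
#' Applies symmetric two-way mutation to expected frequencies:
#' \eqn{p' = p + \mu (1 - 2p)}. `p = 1/2` is the fixed point; boundaries leak
#' inward at rate `mu`.
#'
#' @param p Frequency vector in `[0, 1]`.
#' @param mu Per-locus mutation rate per generation, in `[0, 0.5]`.
#' @return The mutated frequency vector.
#' @export
#' @examples
#' mutation_delta(c(0, 0.5, 1), 2.5e-5)
mutation_delta <- function(p, mu) {
  check_number(mu, "mu", lower = 0, upper = 0.5)
  p + mu * (1 - 2 * p)
}

#' Binomial drift sampling
#'
#' One generation of genetic drift: each frequency is replaced by
#' \eqn{B_i / n} with \eqn{B_i \sim \mathrm{Binomial}(n, p_i)}, independently
#' across loci. `p = 0` and `p = 1` are absorbing.
#'
#' @param p Frequency vector in `[0, 1]`.
#' @param n Haploid population size (`>= 1`).
#' @return The resampled frequency vector.
#' @export
#' @examples
#' set.seed(1)
#' drift_sample(rep(0.5, 5), 100)
drift_sample <- function(p, n) {
  check_number(n, "n", lower = 1)
  rbinom(length(p), as.integer(n), p) / n
}

#' Advance the population one generation
#'
#' Applies, in order: selection ([selection_delta()]), deterministic mutation
#' ([mutation_delta()]), and binomial drift ([drift_sample()]); increments the
#' generation counter. The optimum in force is taken from the schedule in
#' `params` at the *current* generation.
#'
#' @inheritParams selection_delta
#' @param params A [sim_params] object.
#' @return The updated [population_state][initial_state].
#' @export
wf_step <- function(state, arch, params) {
  zopt <- optimum_at(params, state$generation)
  p <- state$p + selection_delta(state, arch, zopt, params$Vs,
                                 method = params$sel_method,
                                 selection = params$selection,
                                 beta = params$beta)
  p <- clamp01(p)
  p <- mutation_delta(p, params$mu)
  state$p <- drift_sample(p, params$n)
  state$generation <- state$generation + 1L
  state
}

#' Run the allele-frequency Wright-Fisher engine
#'
#' Advances the population for `params$generations` generations
#' (selection, then mutation, then drift, each generation), recording the
#' trait mean and genetic variance every generation, thinned per-locus
#' frequency paths, and optional full-frequency snapshots at checkpoint
#' generations.
#'
#' @inheritParams wf_step
#' @param record_every Record per-locus frequency paths every this many
#'   generations (generation 0 and the final generation are always recorded).
#' @param locus_filter Record paths only for loci with `gamma > locus_filter`;
#'   `NULL` (default) records no paths.
#' @param checkpoints Integer vector of generations at which to store the full
#'   frequency vector (for [contribution_decomposition()]); generation 0 and
#'   the final generation are always stored.
#' @param record_vm If `TRUE`, also record the per-generation increment of
#'   genetic variance contributed by the mutation step (the mutational
#'   variance diagnostic `Vm`).
#'
#' @return A list of class `wf_trajectory`:
#' \describe{
#'   \item{summary}{tibble `(generation, trait_mean, var_genetic)`, one row per
#'     generation (including generation 0).}
#'   \item{locus_paths}{tibble `(generation, locus, freq)` for filtered loci.}
#'   \item{checkpoints}{tibble `(generation, locus, freq)` of full snapshots.}
#'   \item{vm}{tibble `(generation, vm)` if `record_vm`.}
#'   \item{final_state}{the final [population_state][initial_state].}
#'   \item{arch, params}{the inputs, for downstream observables.}
#' }
#' @export
#' @examples
#' arch <- sample_architecture(50, seed = 2)
#' par <- sim_params(n = 500, mu = 5e-4, Vs = 5, generations = 100, seed = 9)
#' traj <- wf_run(initial_state(arch, par, seed = 9), arch, par)
#' tail(tidy(traj))
wf_run <- function(state, arch, params, record_every = 1L,
                   locus_filter = NULL, checkpoints = integer(),
                   record_vm = FALSE) {
  stopifnot(inherits(arch, "genetic_architecture"), inherits(params, "sim_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  gens <- params$generations
  gamma <- arch$gamma
  centering <- attr(arch, "centering")
  L <- length(gamma)
  n <- params$n
  mu <- params$mu
  Vs <- params$Vs
  gauss <- params$sel_method == "gaussian"
  directional <- params$selection == "directional"
  wdir <- if (directional) exp(params$beta * gamma) else NULL
  g2 <- gamma^2

  p <- state$p
  if (is.null(p)) stop_invalid("wf_run() needs a frequency-engine state; see wf_run_individual()")
  t0 <- state$generation

  path_loci <- if (is.null(locus_filter)) integer(0) else which(gamma > locus_filter)
  rec_path <- function(t) (t - t0) %% record_every == 0L || t == t0 + gens
  cps <- sort(unique(c(t0, as.integer(checkpoints), t0 + gens)))

  zbar_v <- numeric(gens + 1L)
  vg_v <- numeric(gens + 1L)
  vm_v <- if (record_vm) numeric(gens) else NULL
  paths <- vector("list", gens + 1L)
  snaps <- list()

  record <- function(i, t) {
    zbar_v[i] <<- trait_mean_internal(p, gamma, centering)
    vg_v[i] <<- sum(g2 * p * (1 - p))
    if (length(path_loci) && rec_path(t)) {
      paths[[i]] <<- list(generation = as.numeric(t), freq = p[path_loci])
    }
    if (t %in% cps) snaps[[as.character(t)]] <<- p
  }
  record(1L, t0)

  for (g in seq_len(gens)) {
    t <- t0 + g - 1L           # generation whose optimum applies to this update
    q <- 1 - p
    if (directional) {
      p <- p * wdir / (p * wdir + q)
    } else {
      zopt <- optimum_at(params, t)
      zbar <- trait_mean_internal(p, gamma, centering)
      if (gauss) {
        vc <- g2 * p * q
        Vb <- Vs + pmax(sum(vc) - vc, 0)
        w <- exp((gamma * (zopt - zbar) + g2 * (p - 0.5)) / Vb)
        p <- p * w / (p * w + q)
      } else {
        s <- (gamma * (zopt - zbar) + g2 * (p - 0.5)) / Vs
        p <- clamp01(p + p * q * s)
      }
    }
    if (record_vm) {
      vg_before <- sum(g2 * p * (1 - p))
      p <- p + mu * (1 - 2 * p)
      vm_v[g] <- sum(g2 * p * (1 - p)) - vg_before
    } else {
      p <- p + mu * (1 - 2 * p)
    }
    p <- rbinom(L, n, p) / n
    record(g + 1L, t0 + g)
  }

  generation <- t0 + 0:gens
  locus_paths <- if (length(path_loci)) {
    kept <- !vapply(paths, is.null, logical(1))
    tibble::tibble(
      generation = rep(vapply(paths[kept], `[[`, numeric(1), "generation"),
                       each = length(path_loci)),
      locus = rep(arch$locus[path_loci], sum(kept)),
      freq = unlist(lapply(paths[kept], `[[`, "freq"), use.names = FALSE)
    )
  } else {
    tibble::tibble(generation = integer(), locus = integer(), freq = numeric())
  }
  checkpoint_tbl <- tibble::tibble(
    generation = rep(as.integer(names(snaps)), each = L),
    locus = rep(arch$locus, length(snaps)),
    freq = unlist(snaps, use.names = FALSE)
  )

  structure(
    list(
      summary = tibble::tibble(generation = generation, trait_mean = zbar_v,
                               var_genetic = vg_v),
      locus_paths = locus_paths,
      checkpoints = checkpoint_tbl,
      vm = if (record_vm) tibble::tibble(generation = generation[-1L], vm = vm_v),
      final_state = structure(list(p = p, generation = t0 + gens),
                              class = "population_state"),
      arch = arch, params = params,
      record_every = record_every, locus_filter = locus_filter
    ),
    class = "wf_trajectory"
  )
}

#' Run the individual-based Wright-Fisher engine
#'
#' Desk-scale oracle for the frequency engine. Each generation, each of the
#' `n` haploid offspring picks two parents with probability proportional to
#' fitness (selfing allowed), inherits each locus independently from either
#' parent with probability 1/2 (free recombination), and then mutates each
#' locus copy with probability `mu`. Fitness is
#' \eqn{\exp[-(z - z_{opt})^2/(2 V_s)]} (stabilizing) or \eqn{e^{\beta z}}
#' (directional).
#'
#' @inheritParams wf_run
#' @param state An individual-engine [population_state][initial_state]
#'   (genotype matrix).
#' @return A `wf_trajectory` (summaries computed from realized column-mean
#'   frequencies; genetic variance is the genic \eqn{\sum \gamma^2 p q}).
#' @export
#' @examples
#' arch <- sample_architecture(20, seed = 3)
#' par <- sim_params(n = 100, mu = 1e-3, Vs = 5, generations = 50,
#'                   engine = "individual", seed = 3)
#' traj <- wf_run_individual(initial_state(arch, par, seed = 3), arch, par)
#' glance(traj)
wf_run_individual <- function(state, arch, params, record_every = 1L,
                              locus_filter = NULL, checkpoints = integer()) {
  stopifnot(inherits(arch, "genetic_architecture"), inherits(params, "sim_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  G <- state$genotypes
  if (is.null(G)) stop_invalid("wf_run_individual() needs an individual-engine state")
  gens <- params$generations
  gamma <- arch$gamma
  centering <- attr(arch, "centering")
  n <- nrow(G); L <- ncol(G)
  mu <- params$mu
  offset <- if (identical(centering, "raw")) 0 else sum(gamma) / 2
  t0 <- state$generation
  directional <- params$selection == "directional"

  path_loci <- if (is.null(locus_filter)) integer(0) else which(gamma > locus_filter)
  cps <- sort(unique(c(t0, as.integer(checkpoints), t0 + gens)))

  zbar_v <- numeric(gens + 1L); vg_v <- numeric(gens + 1L)
  paths <- vector("list", gens + 1L); snaps <- list()
  record <- function(i, t) {
    pv <- colMeans(G)
    zbar_v[i] <<- trait_mean_internal(pv, gamma, centering)
    vg_v[i] <<- sum(gamma^2 * pv * (1 - pv))
    if (length(path_loci) &&
        ((t - t0) %% record_every == 0L || t == t0 + gens)) {
      paths[[i]] <<- list(generation = as.numeric(t), freq = pv[path_loci])
    }
    if (t %in% cps) snaps[[as.character(t)]] <<- pv
  }
  record(1L, t0)

  for (g in seq_len(gens)) {
    t <- t0 + g - 1L
    z <- as.vector(G %*% gamma) - offset
    lw <- if (directional) params$beta * z else -(z - optimum_at(params, t))^2 / (2 * params$Vs)
    w <- exp(lw - max(lw))
    pa <- sample.int(n, n, replace = TRUE, prob = w)
    pb <- sample.int(n, n, replace = TRUE, prob = w)
    pick_a <- matrix(runif(n * L) < 0.5, n, L)
    G <- ifelse(pick_a, G[pa, , drop = FALSE], G[pb, , drop = FALSE])
    if (mu > 0) {
      flips <- matrix(runif(n * L) < mu, n, L)
      G <- (G + flips) %% 2L
    }
    record(g + 1L, t0 + g)
  }

  locus_paths <- if (length(path_loci)) {
    kept <- !vapply(paths, is.null, logical(1))
    tibble::tibble(
      generation = rep(vapply(paths[kept], `[[`, numeric(1), "generation"),
                       each = length(path_loci)),
      locus = rep(arch$locus[path_loci], sum(kept)),
      freq = unlist(lapply(paths[kept], `[[`, "freq"), use.names = FALSE)
    )
  } else {
    tibble::tibble(generation = integer(), locus = integer(), freq = numeric())
  }
  checkpoint_tbl <- tibble::tibble(
    generation = rep(as.integer(names(snaps)), each = L),
    locus = rep(arch$locus, length(snaps)),
    freq = unlist(snaps, use.names = FALSE)
  )

  structure(
    list(
      summary = tibble::tibble(generation = t0 + 0:gens, trait_mean = zbar_v,
                               var_genetic = vg_v),
      locus_paths = locus_paths,
      checkpoints = checkpoint_tbl,
      vm = NULL,
      final_state = structure(list(genotypes = G, generation = t0 + gens),
                              class = "population_state"),
      arch = arch, params = params,
      record_every = record_every, locus_filter = locus_filter
    ),
    class = "wf_trajectory"
  )
}

#' @export
print.wf_trajectory <- function(x, ...) {
  s <- x$summary
  cat("<wf_trajectory>", nrow(x$arch), "loci,", nrow(s) - 1L, "generations\n")
  cat("  final trait mean", format(tail(s$trait_mean, 1), digits = 4),
      " final Vg", format(tail(s$var_genetic, 1), digits = 4), "\n")
  invisible(x)
}
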
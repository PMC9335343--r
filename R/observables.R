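#' Trait mean and genetic variance of a population state
#'
#' Under linkage equilibrium for additive biallelic loci the genetic variance
#' is \eqn{V_g = \sum_i \gamma_i^2 p_i q_i}; the trait mean is
#' \eqn{\bar z = \sum_i \gamma_i (p_i - 1/2)} (centered convention) or
#' \eqn{\sum_i \gamma_i p_i} (raw).
#'
#' @param state A [population_state][initial_state] (either engine; the
#'   individual engine uses realized column-mean frequencies).
#' @param arch A [genetic_architecture].
#' @return A one-row tibble with columns `trait_mean` and `var_genetic`.
#' @export
#' @examples
#' arch <- sample_architecture(10, seed = 1)
#' st <- initial_state(arch, sim_params(), mode = "half")
#' trait_moments(st, arch)  # mean 0, Vg = sum(gamma^2)/4
trait_moments <- function(state, arch) {
  p <- state_frequencies(state)
  gamma <- arch$gamma
  tibble::tibble(
    trait_mean = trait_mean_internal(p, gamma, attr(arch, "centering")),
    var_genetic = sum(gamma^2 * p * (1 - p))
  )
}

# full-frequency snapshot at a checkpoint generation, or a classed error
checkpoint_freq <- function(traj, t) {
  cp <- traj$checkpoints
  hit <- cp$generation == t
  if (!any(hit)) {
    abort(sprintf("generation %d was not stored as a checkpoint", t),
          class = "polyadapt_missing_checkpoint")
  }
  cp$freq[hit][order(cp$locus[hit])]
}

#' Per-locus contribution to the change in trait mean
#'
#' Decomposes the change in trait mean between two checkpointed generations
#' into per-locus contributions \eqn{\gamma_i \Delta p_i}. Under the centered
#' convention and the frequency engine the contributions sum *exactly* to
#' \eqn{\bar z(t_1) - \bar z(t_0)}.
#'
#' @param traj A `wf_trajectory` from [wf_run()] whose `checkpoints` include
#'   both generations (see the `checkpoints` argument of [wf_run()]).
#' @param arch The [genetic_architecture] of the run.
#' @param t0,t1 Checkpointed generations (start and end of the interval).
#' @return A tibble `(locus, gamma, delta_p, contribution)` with
#'   `contribution = gamma * delta_p`.
#' @export
contribution_decomposition <- function(traj, arch, t0, t1) {
  p0 <- checkpoint_freq(traj, t0)
  p1 <- checkpoint_freq(traj, t1)
  tibble::tibble(
    locus = arch$locus,
    gamma = arch$gamma,
    delta_p = p1 - p0,
    contribution = arch$gamma * (p1 - p0)
  )
}

#' Classify large-effect loci as substituted or returned
#'
#' After an optimum shift, large-effect "+" alleles rise in frequency while
#' the mean is displaced from the optimum, and then either proceed to fixation
#' ("substituted") or are pushed back to low frequency by stabilizing
#' selection against heterozygosity ("returned"). Among loci with
#' `gamma > effect_threshold`: a locus whose final frequency is at least
#' `fix_threshold` is substituted; a locus whose frequency exceeded 1/2 at
#' some recorded generation at or after `from` but ended below
#' `return_threshold` is returned. The two sets are disjoint by construction.
#'
#' @param traj A `wf_trajectory` whose `locus_paths` cover the loci of
#'   interest (run with `locus_filter <= effect_threshold`).
#' @param arch The [genetic_architecture] of the run.
#' @param effect_threshold Only loci with `gamma` above this are classified
#'   (default 0.2).
#' @param fix_threshold Final frequency at or above which a locus counts as
#'   substituted (default 0.99).
#' @param return_threshold Final frequency below which an excursion counts as
#'   returned (default 0.05).
#' @param from Generation from which excursions are assessed (default: first
#'   recorded generation).
#' @return A list with integer locus-id vectors `substituted` and `returned`.
#' @export
classify_outcomes <- function(traj, arch, effect_threshold = 0.2,
                              fix_threshold = 0.99, return_threshold = 0.05,
                              from = NULL) {
  paths <- traj$locus_paths
  if (nrow(paths) == 0L) {
    abort("trajectory has no recorded locus paths; rerun with `locus_filter`",
          class = "polyadapt_missing_checkpoint")
  }
  eligible <- arch$locus[arch$gamma > effect_threshold]
  paths <- dplyr::filter(paths, .data$locus %in% eligible)
  if (is.null(from)) from <- min(paths$generation)
  t_final <- max(paths$generation)
  per_locus <- paths |>
    dplyr::filter(.data$generation >= from) |>
    dplyr::group_by(.data$locus) |>
    dplyr::summarise(
      final = .data$freq[which.max(.data$generation)],
      peak = max(.data$freq),
      .groups = "drop"
    )
  substituted <- per_locus$locus[per_locus$final >= fix_threshold]
  returned <- per_locus$locus[per_locus$peak >= 0.5 &
                                per_locus$final < return_threshold &
                                per_locus$final < fix_threshold]
  list(substituted = sort(substituted), returned = sort(returned),
       final_generation = t_final)
}

#' Generations until the mean first reaches the new optimum
#'
#' First recorded generation at or after `shift_generation` at which
#' \eqn{|\bar z - z_{opt}|} is at most `tol`. The default tolerance is one
#' equilibrium genetic standard deviation, \eqn{\sqrt{V_g}} measured at the
#' shift generation.
#'
#' @param traj A `wf_trajectory` (summaries are recorded every generation).
#' @param zopt_new The post-shift optimum (trait units).
#' @param tol Tolerance (trait units); default `sqrt(var_genetic)` at the
#'   shift generation.
#' @param shift_generation Generation of the optimum shift (default: first
#'   recorded generation).
#' @return Number of generations after the shift (0 if already within
#'   tolerance at the shift generation); `NA` if never reached.
#' @export
time_to_optimum <- function(traj, zopt_new, tol = NULL, shift_generation = NULL) {
  s <- traj$summary
  if (is.null(shift_generation)) shift_generation <- min(s$generation)
  s <- dplyr::filter(s, .data$generation >= shift_generation)
  if (is.null(tol)) tol <- sqrt(s$var_genetic[1L])
  hit <- which(abs(s$trait_mean - zopt_new) <= tol)
  if (!length(hit)) return(NA_integer_)
  as.integer(s$generation[hit[1L]] - shift_generation)
}

#' Logit-scale locus frequency paths
#'
#' Transforms recorded locus paths to \eqn{\mathrm{logit}(p) = \log(p/(1-p))},
#' which expands resolution near 0 and 1. Frequencies are clamped to
#' `[clamp, 1 - clamp]` first so every path stays finite; the default clamp is
#' half a copy, `1/(2n)`.
#'
#' @param traj A `wf_trajectory` with recorded `locus_paths`.
#' @param clamp Clamping frequency; default `1/(2 * params$n)`.
#' @return The `locus_paths` tibble with an added `logit` column.
#' @export
logit_paths <- function(traj, clamp = NULL) {
  if (is.null(clamp)) clamp <- 1 / (2 * traj$params$n)
  dplyr::mutate(traj$locus_paths,
                logit = log(clamp01(.data$freq, clamp, 1 - clamp) /
                              (1 - clamp01(.data$freq, clamp, 1 - clamp))))
}

#' Per-generation mutational variance diagnostic
#'
#' The mutational variance \eqn{V_m} is the increment of genetic variance
#' contributed by one round of mutation: \eqn{V_g} after the mutation step
#' minus \eqn{V_g} before it. In a fully infinitesimal world the genetic
#' variance would settle at the neutral mutation-drift balance
#' \eqn{2 N_e V_m}; comparing that figure with the realized equilibrium
#' variance measures how strongly stabilizing selection depresses variation.
#'
#' @param state_before,state_after [population_state][initial_state]s that
#'   differ only by the mutation step.
#' @param arch The [genetic_architecture].
#' @return The scalar \eqn{V_m} (squared trait units per generation).
#' @export
#' @examples
#' arch <- sample_architecture(10, seed = 1)
#' par <- sim_params(n = 100, mu = 1e-3)
#' st <- initial_state(arch, par, mode = "near_fixed_random", seed = 1)
#' st2 <- st; st2$p <- mutation_delta(st$p, par$mu)
#' mutational_variance(st, st2, arch)
mutational_variance <- function(state_before, state_after, arch) {
  trait_moments(state_after, arch)$var_genetic -
    trait_moments(state_before, arch)$var_genetic
}
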
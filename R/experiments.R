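#' Configuration for the optimum-shift protocol
#'
#' Bundles everything needed for the full burn-in / shift / relaxation
#' experiment. Defaults are the study conditions: 1,000 loci with exponential
#' effects of mean 0.12, \eqn{n = 10^4} haploid individuals,
#' \eqn{\mu = 2.5\times 10^{-5}}, \eqn{V_s = 20}, a \eqn{10^4}-generation
#' burn-in to mutation-selection-drift equilibrium, then an instantaneous
#' shift of the optimum from 0 to 10 at time zero followed by \eqn{10^4}
#' further generations.
#'
#' @param L,mean_effect Architecture size and exponential effect-size mean.
#' @param n,mu,Vs Population-genetic parameters (see [sim_params()]).
#' @param burn_in_generations Generations run at the pre-shift optimum.
#' @param shift_from,shift_to Optimum before and after time zero.
#' @param post_shift_generations Generations run after the shift.
#' @param replicates Number of replicate populations (`>= 1`).
#' @param fresh_effects_per_replicate Draw a new architecture per replicate
#'   (`TRUE`, the default, for replicate-averaged quantities) or reuse one
#'   fixed architecture (single-realization behavior).
#' @param record_every Thinning of per-locus frequency paths.
#' @param effect_threshold_panelB Effect threshold for recorded/plotted locus
#'   paths (default 0.3).
#' @param effect_threshold_split Effect threshold defining "large-effect"
#'   loci in contribution splits and substitution counts (default 0.2).
#' @param fix_threshold Final frequency for the substituted classification.
#' @param sel_method Frequency-engine selection closure (see [sim_params()]).
#' @param init_mode Burn-in initialization (see [initial_state()]).
#' @return A list of class `shift_config`.
#' @export
shift_config <- function(L = 1000, mean_effect = 0.12, n = 1e4, mu = 2.5e-5,
                         Vs = 20, burn_in_generations = 1e4, shift_from = 0,
                         shift_to = 10, post_shift_generations = 1e4,
                         replicates = 5, fresh_effects_per_replicate = TRUE,
                         record_every = 10,
                         effect_threshold_panelB = 0.3,
                         effect_threshold_split = 0.2,
                         fix_threshold = 0.99,
                         sel_method = "gaussian",
                         init_mode = "near_fixed_random") {
  check_number(replicates, "replicates", lower = 1)
  check_number(effect_threshold_split, "effect_threshold_split",
               lower = 0, strict_lower = TRUE)
  check_number(effect_threshold_panelB, "effect_threshold_panelB",
               lower = 0, strict_lower = TRUE)
  cfg <- list(L = as.integer(L), mean_effect = mean_effect, n = as.integer(n),
              mu = mu, Vs = Vs,
              burn_in_generations = as.integer(burn_in_generations),
              shift_from = shift_from, shift_to = shift_to,
              post_shift_generations = as.integer(post_shift_generations),
              replicates = as.integer(replicates),
              fresh_effects_per_replicate = fresh_effects_per_replicate,
              record_every = as.integer(record_every),
              effect_threshold_panelB = effect_threshold_panelB,
              effect_threshold_split = effect_threshold_split,
              fix_threshold = fix_threshold,
              sel_method = sel_method, init_mode = init_mode)
  structure(cfg, class = "shift_config")
}

# one burn-in + shift replicate; returns summary row + (optionally) trajectory
run_shift_replicate <- function(cfg, rep_seed, keep_trajectory = FALSE,
                                arch = NULL) {
  set.seed(rep_seed)
  if (is.null(arch)) arch <- sample_architecture(cfg$L, cfg$mean_effect)
  par_burn <- sim_params(n = cfg$n, mu = cfg$mu, Vs = cfg$Vs,
                         optimum = cfg$shift_from,
                         generations = cfg$burn_in_generations,
                         sel_method = cfg$sel_method)
  st <- initial_state(arch, par_burn, mode = cfg$init_mode)
  burn <- wf_run(st, arch, par_burn, record_every = cfg$burn_in_generations)
  eq <- tail(burn$summary, 1L)
  t_shift <- cfg$burn_in_generations

  par_post <- sim_params(n = cfg$n, mu = cfg$mu, Vs = cfg$Vs,
                         optimum = cfg$shift_to,
                         generations = cfg$post_shift_generations,
                         sel_method = cfg$sel_method)
  post <- wf_run(burn$final_state, arch, par_post,
                 record_every = cfg$record_every,
                 locus_filter = cfg$effect_threshold_split,
                 checkpoints = c(t_shift, t_shift + 100L))
  fin <- tail(post$summary, 1L)

  p_pre <- checkpoint_freq(post, t_shift)
  p_fin <- checkpoint_freq(post, t_shift + cfg$post_shift_generations)
  large <- arch$gamma > cfg$effect_threshold_split
  sub <- large & p_fin >= cfg$fix_threshold
  contrib_sub <- sum(arch$gamma[sub] * (p_fin[sub] - p_pre[sub]))

  contrib100 <- contribution_decomposition(post, arch, t_shift, t_shift + 100L)
  split100 <- sum(contrib100$contribution[large])
  total100 <- sum(contrib100$contribution)

  row <- tibble::tibble(
    seed = rep_seed,
    vg_eq = eq$var_genetic,
    z_eq = eq$trait_mean,
    time_to_optimum = time_to_optimum(post, cfg$shift_to,
                                      tol = sqrt(eq$var_genetic),
                                      shift_generation = t_shift),
    dz_ultimate = fin$trait_mean - eq$trait_mean,
    vg_final = fin$var_genetic,
    vg_peak = max(post$summary$var_genetic),
    n_large = sum(large),
    n_substituted = sum(sub & p_pre < 0.5),
    contrib_substituted = contrib_sub,
    contrib_large_100 = split100,
    total_100 = total100
  )
  list(row = row, trajectory = if (keep_trajectory) post, arch = arch)
}

#' Run the full optimum-shift experiment
#'
#' For each replicate: sample an architecture, burn in to
#' mutation-selection-drift equilibrium, record the equilibrium variance,
#' shift the optimum instantaneously at time zero, run the post-shift phase,
#' and compute the response observables. Attaches the diffusion-approximation
#' prediction of the equilibrium variance for comparison.
#'
#' @param config A [shift_config()].
#' @param seed Master seed; per-replicate seeds are derived from it.
#' @param keep_trajectory Keep the full `wf_trajectory` of the first
#'   replicate (for plotting); default `TRUE`.
#' @param diffusion Attach the diffusion prediction (default `TRUE`; skip for
#'   speed in throwaway runs).
#' @return A list of class `shift_experiment`: `replicates` (one tibble row per
#'   replicate: equilibrium variance `vg_eq`, `time_to_optimum`,
#'   ultimate change `dz_ultimate`, substitution count and contribution
#'   splits), `aggregate` (replicate means with Monte-Carlo standard
#'   errors), `vg_pred` (diffusion prediction), `config`, `seed`, and
#'   optionally `trajectory` + `arch` of the first replicate.
#' @export
#' @examples
#' \donttest{
#' cfg <- shift_config(L = 100, n = 1000, mu = 2.5e-4, Vs = 2,
#'                     burn_in_generations = 1000,
#'                     post_shift_generations = 1000, shift_to = 3,
#'                     replicates = 2)
#' res <- run_shift_experiment(cfg, seed = 1)
#' glance(res)
#' }
run_shift_experiment <- function(config, seed = 1, keep_trajectory = TRUE,
                                 diffusion = TRUE) {
  stopifnot(inherits(config, "shift_config"))
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, config$replicates)
  shared_arch <- if (!config$fresh_effects_per_replicate) {
    # fixed-architecture mode: one effect draw shared by every replicate
    sample_architecture(config$L, config$mean_effect)
  }
  runs <- purrr::map(seq_len(config$replicates), function(r) {
    out <- run_shift_replicate(config, rep_seeds[r],
                               keep_trajectory = keep_trajectory && r == 1L,
                               arch = shared_arch)
    out$row <- dplyr::mutate(out$row, replicate = r, .before = 1L)
    out
  })
  reps <- purrr::list_rbind(purrr::map(runs, "row"))
  num <- dplyr::select(reps, -"replicate", -"seed")
  aggregate <- tibble::tibble(
    statistic = names(num),
    mean = purrr::map_dbl(num, mean),
    se = purrr::map_dbl(num, ~ sd(.x) / sqrt(length(.x)))
  )
  vg_pred <- if (diffusion) {
    par <- sim_params(n = config$n, mu = config$mu, Vs = config$Vs)
    predict_equilibrium_vg(NULL, par, L = config$L,
                           mean_effect = config$mean_effect)$vg_pred
  } else NA_real_
  structure(
    list(replicates = reps, aggregate = aggregate, vg_pred = vg_pred,
         config = config, seed = seed,
         trajectory = if (keep_trajectory) runs[[1L]]$trajectory,
         arch = if (keep_trajectory) runs[[1L]]$arch),
    class = "shift_experiment"
  )
}

#' @export
print.shift_experiment <- function(x, ...) {
  cat("<shift_experiment>", x$config$replicates, "replicates, L =", x$config$L,
      ", n =", x$config$n, "\n")
  cat("  replicate-mean equilibrium Vg:",
      format(mean(x$replicates$vg_eq), digits = 4),
      "(diffusion prediction", format(x$vg_pred, digits = 4), ")\n")
  cat("  mean time to optimum:", format(mean(x$replicates$time_to_optimum),
                                        digits = 3), "generations\n")
  cat("  mean ultimate change in mean:",
      format(mean(x$replicates$dz_ultimate), digits = 4), "\n")
  invisible(x)
}

#' Write / read a run manifest
#'
#' The manifest (JSON) records the full configuration and master seed of a
#' shift experiment; re-running from the manifest reproduces the identical
#' result.
#'
#' @param result A `shift_experiment`.
#' @param path File path for the JSON manifest.
#' @return `write_run_manifest()` returns `path` invisibly;
#'   `read_run_manifest()` returns `list(config, seed)` ready for
#'   [run_shift_experiment()].
#' @export
write_run_manifest <- function(result, path) {
  stopifnot(inherits(result, "shift_experiment"))
  jsonlite::write_json(list(config = unclass(result$config), seed = result$seed),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_run_manifest
#' @export
read_run_manifest <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(shift_config, m$config[setdiff(names(m$config), character(0))])
  list(config = cfg, seed = m$seed)
}

#' Recompute the headline study quantities
#'
#' Runs the full experiment suite at the study conditions and returns the
#' replicate-averaged headline quantities: the equilibrium genetic variance
#' after burn-in (`equilibrium_vg`), the generations needed for the mean to
#' come within one genetic SD of the shifted optimum (`time_to_optimum`),
#' the ultimate change in mean (`ultimate_change`), the summed contribution
#' of ultimately substituted large-effect alleles
#' (`substituted_contribution`), and the Robertson ratio of total directional
#' response to `Ne * R1` (`robertson_ratio`).
#'
#' @param seed Master seed.
#' @param replicates Replicates for the shift experiment.
#' @param post_shift_generations Post-shift run length.
#' @param robertson_replicates Replicates for the directional-selection
#'   experiment.
#' @return A tibble `(id, value, n)`, one row per quantity.
#' @export
acceptance_targets <- function(seed = 1, replicates = 5,
                               post_shift_generations = 5000,
                               robertson_replicates = 200) {
  cfg <- shift_config(replicates = replicates,
                      post_shift_generations = post_shift_generations)
  res <- run_shift_experiment(cfg, seed = seed, keep_trajectory = FALSE,
                              diffusion = FALSE)
  reps <- res$replicates
  rob <- robertson_experiment(n = 200, L = 2000, gamma = 0.01, beta = 0.045,
                              replicates = robertson_replicates,
                              seed = seed + 1L)
  tibble::tibble(
    id = c("t1", "t2", "t3", "t4", "t5"),
    value = c(mean(reps$vg_eq),
              mean(reps$time_to_optimum),
              mean(reps$dz_ultimate),
              mean(reps$contrib_substituted),
              rob$ratio),
    n = c(replicates, replicates, replicates, replicates,
          robertson_replicates)
  )
}
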
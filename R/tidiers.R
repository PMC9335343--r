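#' Tidy a Wright-Fisher trajectory
#'
#' @param x A `wf_trajectory` from [wf_run()] or [wf_run_individual()].
#' @param ... Unused.
#' @return For `tidy()`, the per-generation summary tibble `(generation,
#'   trait_mean, var_genetic)`; for `glance()`, a one-row tibble with the
#'   run dimensions and final moments.
#' @method tidy wf_trajectory
#' @export
tidy.wf_trajectory <- function(x, ...) x$summary

#' @rdname tidy.wf_trajectory
#' @method glance wf_trajectory
#' @export
glance.wf_trajectory <- function(x, ...) {
  s <- x$summary
  tibble::tibble(
    n_loci = nrow(x$arch),
    generations = nrow(s) - 1L,
    trait_mean_final = tail(s$trait_mean, 1L),
    var_genetic_final = tail(s$var_genetic, 1L)
  )
}

#' Tidy a diffusion prediction
#'
#' @param x A `diffusion_prediction` from [predict_equilibrium_vg()].
#' @param ... Unused.
#' @return For `tidy()`, the per-effect table `(gamma, e_pq,
#'   var_contribution)`; for `glance()`, a one-row tibble `(theta, vg_pred)`.
#' @method tidy diffusion_prediction
#' @export
tidy.diffusion_prediction <- function(x, ...) x$per_effect_table

#' @rdname tidy.diffusion_prediction
#' @method glance diffusion_prediction
#' @export
glance.diffusion_prediction <- function(x, ...) {
  tibble::tibble(theta = x$theta, vg_pred = x$vg_pred)
}

#' Tidy an optimum-shift experiment
#'
#' @param x A `shift_experiment` from [run_shift_experiment()].
#' @param ... Unused.
#' @return For `tidy()`, the per-replicate tibble; for `glance()`, a one-row
#'   tibble of replicate means (with the diffusion prediction attached).
#' @method tidy shift_experiment
#' @export
tidy.shift_experiment <- function(x, ...) x$replicates

#' @rdname tidy.shift_experiment
#' @method glance shift_experiment
#' @export
glance.shift_experiment <- function(x, ...) {
  r <- x$replicates
  tibble::tibble(
    replicates = nrow(r),
    vg_eq = mean(r$vg_eq),
    vg_eq_se = sd(r$vg_eq) / sqrt(nrow(r)),
    vg_pred = x$vg_pred,
    time_to_optimum = mean(r$time_to_optimum),
    dz_ultimate = mean(r$dz_ultimate),
    n_substituted = mean(r$n_substituted),
    contrib_substituted = mean(r$contrib_substituted)
  )
}

#' Tidy a Robertson-limit experiment
#'
#' @param x A `robertson_fit` from [robertson_experiment()].
#' @param ... Unused.
#' @return For `tidy()`, a tibble of per-replicate total responses; for
#'   `glance()`, a one-row tibble with the ratio and its standard error.
#' @method tidy robertson_fit
#' @export
tidy.robertson_fit <- function(x, ...) {
  tibble::tibble(replicate = seq_along(x$totals), total_response = x$totals)
}

#' @rdname tidy.robertson_fit
#' @method glance robertson_fit
#' @export
glance.robertson_fit <- function(x, ...) {
  tibble::tibble(
    n = x$n, Ne = x$Ne, L = x$L, beta = x$beta, gamma = x$gamma,
    replicates = x$replicates, R1 = x$R1, mean_total = x$mean_total,
    ratio = x$ratio, se_ratio = x$se_ratio
  )
}
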
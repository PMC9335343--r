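#' Plot a trajectory's trait mean and genetic variance over time
#'
#' @param object A `wf_trajectory`.
#' @param which `"both"` (faceted), `"mean"`, or `"variance"`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot wf_trajectory
#' @export
autoplot.wf_trajectory <- function(object, which = c("both", "mean", "variance"),
                                   ...) {
  which <- match.arg(which)
  long <- tidyr::pivot_longer(object$summary, c("trait_mean", "var_genetic"),
                              names_to = "statistic")
  labs <- c(trait_mean = "trait mean", var_genetic = "genetic variance")
  long$statistic <- factor(labs[long$statistic], levels = labs)
  if (which != "both") {
    long <- long[long$statistic == labs[[if (which == "mean") "trait_mean"
                                          else "var_genetic"]], ]
  }
  ggplot2::ggplot(long, ggplot2::aes(.data$generation, .data$value)) +
    ggplot2::geom_line(color = "steelblue4") +
    ggplot2::facet_wrap(~statistic, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "generation", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot recorded locus frequency paths
#'
#' Frequencies of the "+" allele over time for the recorded (large-effect)
#' loci, on a logit scale by default so that the approach to fixation is
#' visible.
#'
#' @param traj A `wf_trajectory` run with a `locus_filter`.
#' @param logit Plot on the logit scale (default `TRUE`).
#' @param clamp Clamping frequency for the logit transform; default `1/(2n)`.
#' @return A ggplot.
#' @export
plot_locus_paths <- function(traj, logit = TRUE, clamp = NULL) {
  paths <- logit_paths(traj, clamp = clamp)
  y <- if (logit) "logit" else "freq"
  ggplot2::ggplot(paths, ggplot2::aes(.data$generation, .data[[y]],
                                      group = .data$locus)) +
    ggplot2::geom_line(alpha = 0.4, color = "grey30") +
    ggplot2::labs(x = "generation",
                  y = if (logit) "logit '+'-allele frequency"
                      else "'+'-allele frequency") +
    ggplot2::theme_minimal()
}

#' Plot the per-locus contribution decomposition
#'
#' Contribution of each locus to the change in trait mean,
#' \eqn{\gamma \Delta p}, against its effect size. Substituted loci lie on
#' the upper diagonal \eqn{\Delta p = 1}; loci that returned to low
#' frequency lie near zero.
#'
#' @param decomposition A tibble from [contribution_decomposition()].
#' @param effect_threshold Optional vertical reference line.
#' @return A ggplot.
#' @export
plot_contributions <- function(decomposition, effect_threshold = 0.2) {
  g <- ggplot2::ggplot(decomposition,
                       ggplot2::aes(.data$gamma, .data$contribution)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         color = "grey60") +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::labs(x = expression(gamma), y = expression(gamma * Delta * p)) +
    ggplot2::theme_minimal()
  if (!is.null(effect_threshold)) {
    g <- g + ggplot2::geom_vline(xintercept = effect_threshold,
                                 linetype = 3, color = "grey60")
  }
  g
}

#' Plot an optimum-shift experiment
#'
#' Trait mean and genetic variance over time for the stored replicate, with
#' the diffusion-approximation equilibrium variance as a reference line.
#'
#' @param object A `shift_experiment` run with `keep_trajectory = TRUE`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot shift_experiment
#' @export
autoplot.shift_experiment <- function(object, ...) {
  if (is.null(object$trajectory)) {
    abort("no stored trajectory; rerun with `keep_trajectory = TRUE`")
  }
  g <- autoplot.wf_trajectory(object$trajectory)
  if (is.finite(object$vg_pred)) {
    ref <- data.frame(statistic = factor("genetic variance",
                                         levels = c("trait mean",
                                                    "genetic variance")),
                      vg = object$vg_pred)
    g <- g + ggplot2::geom_hline(data = ref,
                                 ggplot2::aes(yintercept = .data$vg),
                                 color = "red", linetype = 2)
  }
  g
}

#' Plot a substitution-efficiency scan
#'
#' Expected excess of favorable substitutions over the neutral expectation,
#' against the number of selected loci at fixed total fitness variance.
#'
#' @param object An `efficiency_scan` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot efficiency_scan
#' @export
autoplot.efficiency_scan <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$L, .data$excess_substitutions)) +
    ggplot2::geom_line(color = "steelblue4") +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "number of selected loci (log scale)",
                  y = "expected excess substitutions") +
    ggplot2::theme_minimal()
}
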
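#' Construct a genetic architecture from a vector of effect sizes
#'
#' A genetic architecture is the set of `L` unlinked, additive, biallelic loci
#' underlying the trait. By convention every effect \eqn{\gamma_i} is positive:
#' the "+" allele at each locus is the one that increases the trait. Under the
#' default `centered` convention the trait of a genotype `x` (a 0/1 vector of
#' "+"-allele indicators) is \eqn{z = \sum_i \gamma_i (x_i - 1/2)}, so that a
#' population in which every locus is at frequency 1/2, or in which the
#' stationary allele-frequency distribution is symmetric, has mean zero. The
#' `raw` convention \eqn{z = \sum_i \gamma_i x_i} is retained for sensitivity
#' checks.
#'
#' @param effects Numeric vector of per-locus additive effects, all `> 0`
#'   (trait units).
#' @param centering `"centered"` (default) or `"raw"`; see Details.
#' @param mean_effect Optional number recording the mean of the sampling
#'   distribution the effects were drawn from (metadata only).
#'
#' @return A tibble of class `genetic_architecture` with columns `locus`
#'   (integer id) and `gamma` (effect size), and attributes `centering` and
#'   `mean_effect`.
#' @seealso [sample_architecture()], [initial_state()]
#' @export
#' @examples
#' genetic_architecture(c(0.3, 0.1, 0.05))
genetic_architecture <- function(effects,
                                 centering = c("centered", "raw"),
                                 mean_effect = NULL) {
  centering <- match.arg(centering)
  if (length(effects) < 1L || !is.numeric(effects) || anyNA(effects)) {
    stop_invalid("`effects` must be a non-empty numeric vector")
  }
  if (any(effects <= 0)) {
    stop_invalid("all effects must be > 0 (the '+' allele carries the positive effect)")
  }
  out <- tibble::tibble(locus = seq_along(effects), gamma = as.numeric(effects))
  attr(out, "centering") <- centering
  attr(out, "mean_effect") <- mean_effect
  class(out) <- c("genetic_architecture", class(out))
  out
}

#' Sample a synthetic genetic architecture
#'
#' Draws `L` i.i.d. effect sizes from an exponential distribution. The study
#' conditions emulated throughout the package are 1,000 biallelic loci with
#' exponential effects of mean 0.12 trait units.
#'
#' @param L Number of loci (`>= 1`).
#' @param mean_effect Mean of the exponential effect-size distribution
#'   (trait units, `> 0`). Default 0.12.
#' @param seed Optional integer seed for reproducibility; when `NULL` the
#'   current RNG stream is used.
#' @inheritParams genetic_architecture
#'
#' @return A [genetic_architecture] tibble (columns `locus`, `gamma`).
#' @export
#' @examples
#' arch <- sample_architecture(1000, mean_effect = 0.12, seed = 1)
#' mean(arch$gamma)
sample_architecture <- function(L = 1000, mean_effect = 0.12, seed = NULL,
                                centering = c("centered", "raw")) {
  check_number(L, "L", lower = 1)
  check_number(mean_effect, "mean_effect", lower = 0, strict_lower = TRUE)
  if (!is.null(seed)) set.seed(seed)
  effects <- rexp(as.integer(L), rate = 1 / mean_effect)
  genetic_architecture(effects, centering = match.arg(centering),
                       mean_effect = mean_effect)
}

#' Simulation parameters for the Wright-Fisher engines
#'
#' Bundles the population-genetic parameters of a run. The haploid census size
#' `n` is also the effective size used by the drift term (one binomial draw of
#' `n` trials per locus per generation). Defaults are the study conditions:
#' `n = 1e4`, `mu = 2.5e-5` (so \eqn{\theta = 2 n \mu = 0.5}), `Vs = 20`.
#'
#' @param n Haploid census size (`>= 2`).
#' @param mu Per-locus symmetric mutation rate per generation, in `[0, 0.5]`.
#' @param Vs Width of Gaussian stabilizing selection (squared trait units,
#'   `> 0`); fitness is \eqn{\exp[-(z - z_{opt})^2 / (2 V_s)]}.
#' @param optimum Optimum schedule: either a single number (constant optimum)
#'   or a data frame with columns `generation` and `zopt` giving a step
#'   function (the optimum from each listed generation onward).
#' @param generations Total generations to simulate (`>= 0`).
#' @param seed Optional integer seed applied at the start of [wf_run()].
#' @param engine `"frequency"` (vectorized mean-field, the default) or
#'   `"individual"` (explicit genotype matrix; desk-scale oracle).
#' @param selection `"stabilizing"` (Gaussian, default) or `"directional"`
#'   (fitness \eqn{\propto e^{\beta z}}, used for the limits-to-selection
#'   experiments).
#' @param beta Directional selection gradient (per trait unit); ignored for
#'   stabilizing selection.
#' @param sel_method Closure used by the frequency engine for the stabilizing
#'   per-locus selection update: `"gaussian"` (exact Gaussian-background
#'   integral, default) or `"first_order"` (first order in 1/Vs; faster,
#'   matches the analytic theory).
#'
#' @return A list of class `sim_params`.
#' @export
#' @examples
#' sim_params(n = 1e4, mu = 2.5e-5, Vs = 20, generations = 100)
sim_params <- function(n = 1e4, mu = 2.5e-5, Vs = 20, optimum = 0,
                       generations = 0, seed = NULL,
                       engine = c("frequency", "individual"),
                       selection = c("stabilizing", "directional"),
                       beta = 0,
                       sel_method = c("gaussian", "first_order")) {
  check_number(n, "n", lower = 2)
  check_number(mu, "mu", lower = 0, upper = 0.5)
  check_number(Vs, "Vs", lower = 0, strict_lower = TRUE)
  check_number(generations, "generations", lower = 0)
  check_number(beta, "beta")
  if (is.data.frame(optimum)) {
    if (!all(c("generation", "zopt") %in% names(optimum)) || nrow(optimum) < 1L) {
      stop_invalid("`optimum` data frame needs columns `generation` and `zopt`")
    }
    optimum <- optimum[order(optimum$generation), c("generation", "zopt")]
  } else {
    check_number(optimum, "optimum")
  }
  structure(
    list(n = as.integer(n), mu = mu, Vs = Vs, optimum = optimum,
         generations = as.integer(generations), seed = seed,
         engine = match.arg(engine), selection = match.arg(selection),
         beta = beta, sel_method = match.arg(sel_method)),
    class = "sim_params"
  )
}

# optimum value in force at generation t (step schedule)
optimum_at <- function(params, t) {
  opt <- params$optimum
  if (!is.data.frame(opt)) return(opt)
  i <- findInterval(t, opt$generation)
  if (i < 1L) opt$zopt[1L] else opt$zopt[i]
}

#' Initial population state
#'
#' Builds the starting state for a run. `mode = "half"` places every locus at
#' frequency exactly 1/2; `mode = "near_fixed_random"` (the burn-in default)
#' fixes each locus at 0 or 1 with probability 1/2 each, which equilibrates
#' fastest when \eqn{\theta = 2 n \mu < 1} and the stationary density is
#' concentrated near the boundaries.
#'
#' @param arch A [genetic_architecture].
#' @param params A [sim_params] object; `params$engine` decides whether the
#'   state stores a frequency vector or an `n x L` genotype matrix.
#' @param mode `"near_fixed_random"` (default) or `"half"`.
#' @param seed Optional seed for the random initialization.
#'
#' @return A list of class `population_state` with elements `p` (frequency
#'   vector, frequency engine) or `genotypes` (binary matrix, individual
#'   engine) and `generation = 0`.
#' @export
#' @examples
#' arch <- sample_architecture(10, seed = 1)
#' initial_state(arch, sim_params(n = 100), mode = "half")$p
initial_state <- function(arch, params,
                          mode = c("near_fixed_random", "half"),
                          seed = NULL) {
  stopifnot(inherits(arch, "genetic_architecture"), inherits(params, "sim_params"))
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  L <- nrow(arch)
  p <- if (mode == "half") rep(0.5, L) else as.numeric(rbinom(L, 1L, 0.5))
  if (params$engine == "individual") {
    n <- params$n
    if (mode == "half") {
      # exactly n/2 carriers per locus so realized frequencies are 1/2
      half <- floor(n / 2)
      G <- vapply(seq_len(L), function(i) {
        g <- integer(n); g[sample.int(n, half)] <- 1L; g
      }, integer(n))
    } else {
      G <- matrix(rep(as.integer(p), each = n), nrow = n)
    }
    state <- list(genotypes = G, generation = 0L)
  } else {
    state <- list(p = p, generation = 0L)
  }
  structure(state, class = "population_state")
}

#' @export
print.population_state <- function(x, ...) {
  if (!is.null(x$p)) {
    cat("<population_state> frequency engine,", length(x$p), "loci, generation",
        x$generation, "\n")
  } else {
    cat("<population_state> individual engine,", nrow(x$genotypes), "x",
        ncol(x$genotypes), "genotype matrix, generation", x$generation, "\n")
  }
  invisible(x)
}

# realized "+"-allele frequencies regardless of engine
state_frequencies <- function(state) {
  if (!is.null(state$p)) state$p else colMeans(state$genotypes)
}

#' Serialize / read a genetic architecture
#'
#' Writes the per-locus table as TSV (`locus`, `gamma`) next to a JSON sidecar
#' (`<path>.json`) carrying the metadata (centering convention, sampling mean).
#'
#' @param arch A [genetic_architecture].
#' @param path Path of the TSV file to write.
#' @return `write_architecture()` returns `path` invisibly;
#'   `read_architecture()` returns the reconstructed [genetic_architecture].
#' @export
write_architecture <- function(arch, path) {
  stopifnot(inherits(arch, "genetic_architecture"))
  readr::write_tsv(tibble::as_tibble(arch)[c("locus", "gamma")], path)
  meta <- list(L = nrow(arch), centering = attr(arch, "centering"),
               mean_effect = attr(arch, "mean_effect"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_architecture
#' @export
read_architecture <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  meta_path <- paste0(path, ".json")
  centering <- "centered"
  mean_effect <- NULL
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path)
    centering <- meta$centering %||% "centered"
    mean_effect <- meta$mean_effect
  }
  genetic_architecture(tab$gamma, centering = centering,
                       mean_effect = mean_effect)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
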